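# End-to-end orchestration: DBH screening -> diversity -> maternity
# assignment -> pedigree -> Moran's I -> model comparison -> variance
# components, heritability and ranked breeding values.

#' Screen records by a DBH threshold
#'
#' Trees strictly above the threshold are excluded (boundary values are
#' kept), the convention used to strip pre-existing older trees from a
#' reforested stand before analysis.
#'
#' @param records data.frame with a `dbh` column (cm).
#' @param threshold cm, default 30.
#' @return list with `kept`, `excluded` (with a `reason` column) and
#'   `counts`.
#' @export
screen_by_dbh <- function(records, threshold = 30) {
  stopifnot(threshold > 0)
  out <- records$dbh > threshold
  excluded <- records[out, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- sprintf("dbh > %g cm", threshold)
  list(kept = records[!out, , drop = FALSE],
       excluded = excluded,
       counts = c(total = nrow(records), kept = sum(!out),
                  excluded = sum(out)))
}

#' Read a phenotype/coordinate table (id,x,y,dbh[,height][,group])
#' @param path CSV path.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "dbh")
  if (!all(need %in% names(d)))
    stop("phenotype CSV needs columns ", paste(need, collapse = ","))
  if (any(!is.finite(d$x)) || any(!is.finite(d$y)))
    stop("non-finite coordinates")
  if (any(d$dbh <= 0)) stop("dbh must be positive")
  d
}

#' Pipeline configuration
#'
#' @param genotypes,phenotypes input CSV paths (`NULL` allowed when the
#'   corresponding stages are skipped).
#' @param genotype_dialect `"genalex_csv"` or `"long_csv"`.
#' @param mother_group,offspring_groups group labels.
#' @param dbh_screen_threshold cm (default 30).
#' @param parentage a [parentage_config()].
#' @param grid_dims rasterization grid (default c(450, 450)).
#' @param structures residual structures to compare.
#' @param seed root seed; all stage seeds derive from it.
#' @param out_dir output directory.
#' @export
pipeline_config <- function(genotypes = NULL, phenotypes = NULL,
                            genotype_dialect = "genalex_csv",
                            mother_group = "PT",
                            offspring_groups = c("HC", "HS"),
                            dbh_screen_threshold = 30,
                            parentage = parentage_config(),
                            grid_dims = c(450L, 450L),
                            structures = c("none", "exponential", "gaussian",
                                           "spherical", "linear", "rational",
                                           "ar1", "ar1xar1"),
                            seed = 1L, out_dir = "orchardgt_out") {
  stopifnot(dbh_screen_threshold > 0)
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 genotype_dialect = genotype_dialect,
                 mother_group = mother_group,
                 offspring_groups = offspring_groups,
                 dbh_screen_threshold = dbh_screen_threshold,
                 parentage = parentage, grid_dims = grid_dims,
                 structures = structures, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full genetic-testing pipeline
#'
#' Stages, per offspring cohort: (1) DBH screening; (2) diversity summary
#' across groups; (3) maternity assignment with simulated confidence
#' thresholds; (4) Moran's I on DBH; (5) rasterization and AICc comparison
#' of residual structures; (6) heritability and ranked breeding values
#' from the best model.  All randomness derives from `config$seed`.
#' Writes CSV/JSON artifacts under `config$out_dir` and returns them
#' invisibly.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list of class `pipeline_result` with elements `diversity`,
#'   `informativeness`, `parentage`, `tier_table`, `moran`, `comparison`,
#'   `variances`, `heritability`, `breeding_values`, `screen`, `log`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  seeds <- split_seed(config$seed, 4L)
  tab <- read_genotype_table(config$genotypes, config$genotype_dialect)
  phen <- read_phenotypes(config$phenotypes)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("stage 1: DBH screening at %g cm", config$dbh_screen_threshold)
  scr <- screen_by_dbh(phen, config$dbh_screen_threshold)
  say("  kept %d / excluded %d of %d", scr$counts["kept"],
      scr$counts["excluded"], scr$counts["total"])
  phen <- scr$kept

  say("stage 2: diversity statistics")
  div <- diversity_table(tab, c(config$mother_group,
                                config$offspring_groups))
  af <- allele_frequencies(tab)
  info <- non_exclusion(af)
  utils::write.csv(div, file.path(config$out_dir, "diversity.csv"),
                   row.names = FALSE)

  say("stage 3: maternity assignment (%d simulations)",
      config$parentage$n_sim)
  pcfg <- config$parentage
  pcfg$seed <- seeds[1L]
  par_res <- list()
  tier_tabs <- list()
  peds <- list()
  for (g in config$offspring_groups) {
    pr <- assign_maternity(tab, g, config$mother_group, pcfg)
    par_res[[g]] <- pr
    tt <- tier_summary(pr)
    tier_tabs[[g]] <- cbind(group = g, tt)
    peds[[g]] <- pr$pedigree
    utils::write.csv(pr$results,
                     file.path(config$out_dir,
                               sprintf("parentage_%s.csv", g)),
                     row.names = FALSE)
  }
  tier_table <- do.call(rbind, tier_tabs)
  utils::write.csv(tier_table,
                   file.path(config$out_dir, "assignment_tiers.csv"),
                   row.names = FALSE)
  ped <- do.call(rbind, peds)
  rownames(ped) <- NULL
  write_pedigree(ped, file.path(config$out_dir, "pedigree.csv"))

  # phenotyped offspring only, with dams from the reconstructed pedigree
  phen$dam <- ped$dam[match(phen$id, ped$id)]
  phen <- phen[phen$id %in% ped$id, , drop = FALSE]
  if (nrow(phen) < 10L)
    stop("stage 4: fewer than 10 phenotyped offspring after screening")

  # stages 4-6 run per site (offspring cohort): distinct plantations have
  # distinct spatial fields, so sites are modelled separately (diversity,
  # above, is compared jointly).  Artifact names are unsuffixed for a
  # single site, suffixed _<site> otherwise.
  ped_full <- rbind(
    data.frame(id = setdiff(stats::na.omit(ped$dam), ped$id),
               dam = NA_character_, sire = NA_character_),
    ped)
  A <- build_A(ped_full)
  sites <- if ("group" %in% names(phen) &&
               length(unique(phen$group)) > 1L) {
    split(phen, phen$group)
  } else list(phen)
  suffix <- function(base, site_name) {
    if (length(sites) == 1L) base else
      sub("(\\.[a-z]+)$", sprintf("_%s\\1", site_name), base)
  }
  moran <- list(); cmp <- list(); var_tab <- list(); bv <- list()
  best_name <- character(0); h2 <- numeric(0)
  for (si in seq_along(sites)) {
    sp <- sites[[si]]
    site <- names(sites)[si] %||% "site1"
    if (nrow(sp) < 10L)
      stop("stage 4 (", site, "): fewer than 10 phenotyped offspring")
    say("stage 4 [%s]: Moran's I on DBH (n = %d)", site, nrow(sp))
    moran[[si]] <- morans_i(sp$dbh, sp[, c("x", "y")], n_perm = 999,
                            seed = seeds[2L])
    say("stage 5 [%s]: rasterization %dx%d + model comparison", site,
        config$grid_dims[1L], config$grid_dims[2L])
    grid <- rasterize(sp, config$grid_dims[1L], config$grid_dims[2L])
    cmp[[si]] <- compare_models(sp, A, grid,
                                structures = config$structures,
                                seed = seeds[3L])
    utils::write.csv(as.data.frame(cmp[[si]]),
                     file.path(config$out_dir,
                               suffix("model_comparison.csv", site)),
                     row.names = FALSE)

    best_name[si] <- cmp[[si]]$model[1L]
    best <- attr(cmp[[si]], "fits")[[best_name[si]]]
    h2[si] <- best$h2
    say("stage 6 [%s]: best model %s (AICc %.1f), h2 = %.3f", site,
        best_name[si], best$aicc, best$h2)
    est <- unlist(best$estimates)
    var_tab[[si]] <- data.frame(component = names(est),
                                estimate = unname(est),
                                se = unname(best$se[names(est)]))
    utils::write.csv(var_tab[[si]],
                     file.path(config$out_dir,
                               suffix("variances.csv", site)),
                     row.names = FALSE)

    b <- blup(best)
    b$group <- ifelse(b$id %in% sp$id, "offspring", "mother")
    b$model <- best_name[si]
    bv[[si]] <- b
    utils::write.csv(b[b$group == "offspring" & b$id %in% sp$id, ],
                     file.path(config$out_dir,
                               suffix("breeding_values_offspring.csv",
                                      site)),
                     row.names = FALSE)
    utils::write.csv(b[b$group == "mother", ],
                     file.path(config$out_dir,
                               suffix("breeding_values_mothers.csv", site)),
                     row.names = FALSE)
  }
  names(moran) <- names(cmp) <- names(var_tab) <- names(bv) <-
    names(best_name) <- names(h2) <- names(sites)
  if (length(sites) == 1L) {   # unwrap for the common single-site case
    moran <- moran[[1L]]; cmp <- cmp[[1L]]; var_tab <- var_tab[[1L]]
    bv <- bv[[1L]]; best_name <- best_name[[1L]]; h2 <- h2[[1L]]
  }

  log <- list(seed = config$seed, config_hash = config_hash(config),
              stage_seeds = seeds,
              n_genotyped = length(tab$ids), screen = as.list(scr$counts),
              n_phenotyped = nrow(phen),
              package_version = as.character(utils::packageVersion("orchardgt")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  structure(list(diversity = div, informativeness = info,
                 parentage = par_res, tier_table = tier_table,
                 moran = moran, comparison = cmp,
                 variances = var_tab, heritability = h2,
                 breeding_values = bv, screen = scr, best_model = best_name,
                 log = log),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("orchardgt pipeline result\n")
  cat("  screening:", x$log$screen$kept, "kept /",
      x$log$screen$excluded, "excluded\n")
  print(x$tier_table)
  mor <- if (inherits(x$moran, "moran_result")) list(x$moran) else x$moran
  for (i in seq_along(mor))
    cat(sprintf("  Moran's I%s: %.3f (p = %.3g)\n",
                if (length(mor) > 1L) paste0(" [", names(mor)[i], "]") else "",
                mor[[i]]$I, mor[[i]]$p_value))
  for (i in seq_along(x$heritability))
    cat(sprintf("  best model%s: %s, h2 = %.3f\n",
                if (length(x$heritability) > 1L)
                  paste0(" [", names(x$heritability)[i], "]") else "",
                x$best_model[i], x$heritability[i]))
  invisible(x)
}

#' Write a fit report: JSON summary plus breeding-value CSV
#'
#' @param fit an `orchard_fit`.
#' @param dir output directory (created if needed).
#' @param model_name label recorded in the outputs.
#' @param offspring_ids ids to label as offspring (others are mothers).
#' @return paths of the two files, invisibly.
#' @export
write_fit_report <- function(fit, dir, model_name = NULL,
                             offspring_ids = fit$data_ids) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model_name <- model_name %||%
    paste0(fit$spec$genetic, "+", fit$spec$structure$kind)
  est <- unlist(fit$estimates)
  rep <- list(model = model_name,
              estimates = as.list(est),
              se = as.list(fit$se[names(est)]),
              intercept = fit$intercept,
              loglik = fit$loglik, k = fit$k, n = fit$n,
              aicc = fit$aicc, h2 = fit$h2,
              converged = fit$converged)
  jp <- file.path(dir, "fit.json")
  jsonlite::write_json(rep, jp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  bv <- blup(fit)
  bv$group <- ifelse(bv$id %in% offspring_ids, "offspring", "mother")
  names(bv)[names(bv) == "ebv"] <- "ebv_cm"
  bv$model <- model_name
  cp <- file.path(dir, "breeding_values.csv")
  utils::write.csv(bv[, c("id", "group", "ebv_cm", "rank", "model")], cp,
                   row.names = FALSE)
  invisible(c(jp, cp))
}

# polynomial rolling hash of the deparsed config object, for run logs
config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic orchard), `diversity`,
#' `assign`, `moran`, `compare`, `run` (full pipeline).  Options use
#' `--key value` pairs; `--config path.json` loads a JSON file whose
#' fields mirror [pipeline_config()].  Invoke from a shell as
#' `Rscript -e 'orchardgt::orchard_cli()' <subcommand> [options]`.
#'
#' @param args character vector (default: command line).
#' @return exit status, invisibly.
#' @export
orchard_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: orchard_cli <simulate|diversity|assign|moran|compare|run>",
        "[--config cfg.json] [--key value ...]\n")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opts <- parse_cli_opts(args[-1L])
  cfg_list <- list()
  if (!is.null(opts$config))
    cfg_list <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
  opts$config <- NULL
  cfg_list[names(opts)] <- opts
  seed <- as.integer(cfg_list$seed %||% 1L)
  out_dir <- cfg_list$out_dir %||% "orchardgt_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(cmd,
    simulate = {
      af <- simulate_allele_frequencies(seed = seed)
      orch <- simulate_orchard(af,
                               n_mothers = as.integer(cfg_list$n_mothers %||% 145L),
                               n_offspring = as.integer(cfg_list$n_offspring %||% 188L),
                               error_rate = as.numeric(cfg_list$error_rate %||% 0),
                               seed = seed + 1L)
      sim <- simulate_phenotypes(orch$pedigree, default_truth(),
                                 grid_dims = c(30L, 30L), seed = seed + 2L)
      write_genotype_table(orch$table, file.path(out_dir, "genotypes.csv"))
      utils::write.csv(sim$records[, c("id", "x", "y", "dbh", "group")],
                       file.path(out_dir, "phenotypes.csv"),
                       row.names = FALSE)
      truth <- c(default_truth(), list(seed = seed))
      jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      message("wrote synthetic orchard to ", out_dir)
    },
    diversity = {
      tab <- read_genotype_table(cfg_list$genotypes,
                                 cfg_list$genotype_dialect %||% "genalex_csv")
      div <- diversity_table(tab)
      utils::write.csv(div, file.path(out_dir, "diversity.csv"),
                       row.names = FALSE)
      print(utils::head(div, 20))
    },
    assign = {
      tab <- read_genotype_table(cfg_list$genotypes,
                                 cfg_list$genotype_dialect %||% "genalex_csv")
      pr <- assign_maternity(tab,
                             cfg_list$offspring_group %||% "HC",
                             cfg_list$mother_group %||% "PT",
                             parentage_config(seed = seed))
      utils::write.csv(pr$results, file.path(out_dir, "parentage.csv"),
                       row.names = FALSE)
      write_pedigree(pr$pedigree, file.path(out_dir, "pedigree.csv"))
      print(pr)
    },
    moran = {
      phen <- read_phenotypes(cfg_list$phenotypes)
      print(morans_i(phen$dbh, phen[, c("x", "y")], n_perm = 999,
                     seed = seed))
    },
    fit = {
      phen <- read_phenotypes(cfg_list$phenotypes)
      ped <- read_pedigree(cfg_list$pedigree)
      phen$dam <- ped$dam[match(phen$id, ped$id)]
      ped_full <- rbind(
        data.frame(id = setdiff(stats::na.omit(ped$dam), ped$id),
                   dam = NA_character_, sire = NA_character_), ped)
      A <- build_A(ped_full)
      gd <- as.integer(cfg_list$grid_dims %||% c(450L, 450L))
      grid <- rasterize(phen, gd[1L], gd[2L])
      spec <- model_spec(cfg_list$structure %||% "ar1xar1")
      f <- fit_spatial_model(spec, phen, A = A, grid = grid, seed = seed)
      write_fit_report(f, out_dir)
      print(f)
    },
    compare = {
      phen <- read_phenotypes(cfg_list$phenotypes)
      ped <- read_pedigree(cfg_list$pedigree)
      phen$dam <- ped$dam[match(phen$id, ped$id)]
      ped_full <- rbind(
        data.frame(id = setdiff(stats::na.omit(ped$dam), ped$id),
                   dam = NA_character_, sire = NA_character_), ped)
      A <- build_A(ped_full)
      gd <- as.integer(cfg_list$grid_dims %||% c(450L, 450L))
      grid <- rasterize(phen, gd[1L], gd[2L])
      cmp <- compare_models(phen, A, grid, seed = seed)
      utils::write.csv(as.data.frame(cmp),
                       file.path(out_dir, "model_comparison.csv"),
                       row.names = FALSE)
      print(as.data.frame(cmp))
    },
    run = {
      cfg <- pipeline_config(
        genotypes = cfg_list$genotypes,
        phenotypes = cfg_list$phenotypes,
        genotype_dialect = cfg_list$genotype_dialect %||% "genalex_csv",
        mother_group = cfg_list$mother_group %||% "PT",
        offspring_groups = cfg_list$offspring_groups %||% "HC",
        dbh_screen_threshold =
          as.numeric(cfg_list$dbh_screen_threshold %||% 30),
        grid_dims = as.integer(cfg_list$grid_dims %||% c(450L, 450L)),
        seed = seed, out_dir = out_dir)
      print(run_pipeline(cfg))
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("expected --option, got ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("missing value for --", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}
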