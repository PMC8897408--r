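# End-to-end orchestration: simulate -> genotype -> {windows/trees, D-scan,
# Fst-scan, structure}, with structured logging, a manifest of outputs and a
# single run report.

#' Run configuration
#'
#' Exactly one input source: `sim` (a [species_tree_config()] or argument
#' list for one) or `input_vcf` (path). Stages not applicable to the input
#' are skipped with a report note. All defaults are echoed into the report.
#'
#' @param out_dir output directory (created).
#' @param seed global seed; every stage derives sub-seeds from it.
#' @param sim a `species_tree_config`, an argument list for one, or NULL.
#' @param input_vcf multi-sample VCF path, or NULL.
#' @param pop_map named character vector individual -> taxon, or a TSV path.
#' @param depth,qual pileup simulation depth and phred quality.
#' @param filters a [filter_config()].
#' @param divergence a [divergence_config()].
#' @param stages character vector of stages to run (subset of simulate,
#'   genotype, windows, trees, dstat, fst, structure).
#' @param trees list(group_map = taxon -> group named vector, outgroup =
#'   group name); NULL derives groups from the population map with the two
#'   rarest taxa merged into the outgroup when 5 taxa are present.
#' @param dstat list(outgroup = taxon, mode, sisters).
#' @param fst list(pops = two taxa, window, z_cutoff).
#' @param structure list(K_range, reps, thin_bp).
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, sim = NULL, input_vcf = NULL,
                       pop_map = NULL, depth = 30, qual = 30,
                       filters = filter_config(),
                       divergence = divergence_config(),
                       stages = c("simulate", "genotype", "windows", "trees",
                                  "dstat", "fst", "structure"),
                       trees = NULL, dstat = NULL, fst = NULL,
                       structure = list(K_range = 1:5, reps = 3, thin_bp = 0)) {
  if (is.null(sim) == is.null(input_vcf)) {
    stop("exactly one input source: sim or input_vcf")
  }
  if (!is.null(input_vcf) && !file.exists(input_vcf)) {
    stop("input_vcf does not exist: ", input_vcf)
  }
  if (is.list(sim) && !inherits(sim, "species_tree_config")) {
    sim <- do.call(species_tree_config, c(sim, list(seed = as.integer(seed))))
  }
  if (is.character(pop_map) && length(pop_map) == 1 && is.null(names(pop_map))) {
    pop_map <- read_population_map(pop_map)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 input_vcf = input_vcf, pop_map = pop_map, depth = depth,
                 qual = qual, filters = filters, divergence = divergence,
                 stages = stages, trees = trees, dstat = dstat, fst = fst,
                 structure_opts = structure),
            class = "run_config")
}

log_stage <- function(con, stage, level, msg, t0) {
  line <- sprintf("[%s] %s %s (%.1fs)", stage, level, msg,
                  as.numeric(proc.time()["elapsed"]) - t0)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full pipeline
#'
#' Stages execute in dependency order; a failing stage halts its dependents
#' but independent branches complete, and the report records the failure.
#' Re-running with the same config and seed reproduces byte-identical
#' outputs; the manifest lists every artifact with its md5 checksum.
#'
#' @param config a [run_config()].
#' @return object of class `run_report`: per-stage status, counts and
#'   wall-clock, the parameter echo, the seed and the output manifest.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(config$out_dir, "run.log"), "w")
  on.exit(close(logcon))
  t0 <- as.numeric(proc.time()["elapsed"])
  report <- list(seed = config$seed, version = as.character(utils::packageVersion("museopop")),
                 stages = list(), counts = list(), params = config[setdiff(names(config), "sim")])
  state <- new.env(parent = emptyenv())
  state$pop_map <- config$pop_map
  done <- character(0); failed <- character(0)
  deps <- list(simulate = character(0), genotype = "simulate",
               windows = "genotype", trees = "windows", dstat = "genotype",
               fst = "genotype", structure = "genotype")
  if (!is.null(config$input_vcf)) deps$genotype <- character(0)
  run_stage <- function(stage, fun) {
    if (!(stage %in% config$stages)) return(invisible())
    if (length(setdiff(deps[[stage]], done))) {
      report$stages[[stage]] <<- list(status = "skipped (dependency failed or off)")
      return(invisible())
    }
    ts <- as.numeric(proc.time()["elapsed"])
    res <- tryCatch({ fun(); "ok" },
                    error = function(e) paste("failed:", conditionMessage(e)))
    el <- as.numeric(proc.time()["elapsed"]) - ts
    report$stages[[stage]] <<- list(status = res, elapsed = el)
    if (identical(res, "ok")) done <<- c(done, stage) else failed <<- c(failed, stage)
    log_stage(logcon, stage, if (identical(res, "ok")) "INFO" else "ERROR", res, t0)
  }

  run_stage("simulate", function() {
    sim <- config$sim
    gen <- simulate_genealogies(sim)
    panel <- mutate_sequences(gen)
    piles <- generate_pileups(panel, depth = config$depth, qual = config$qual,
                              depth_track = TRUE, seed = config$seed)
    state$gen <- gen; state$panel <- panel; state$piles <- piles
    state$truth <- truth_set(gen)
    if (is.null(state$pop_map)) {
      state$pop_map <- stats::setNames(gen$sheet$ind_pop, gen$sheet$individuals)
    }
    yaml::write_yaml(list(seed = sim$seed, mu = sim$mu,
                          window_length = sim$window_length,
                          n_windows = sim$n_windows,
                          labels = sim$labels,
                          samples = as.list(sim$samples),
                          ne = as.list(sim$ne)),
                     file.path(config$out_dir, "sim_config.yaml"))
    write_tsv(data.frame(individual = names(state$pop_map),
                         taxon = unname(state$pop_map)),
              file.path(config$out_dir, "pop_map.tsv"))
    report$counts$windows_simulated <<- sim$n_windows
    report$counts$segregating_sites <<- sum(vapply(gen$windows, function(w) length(w$pos), numeric(1)))
  })

  run_stage("genotype", function() {
    if (!is.null(config$input_vcf)) {
      st <- read_vcf_site_table(config$input_vcf)
      st <- filter_sites(st, config$filters)
    } else {
      st <- call_snps(state$piles, config$filters)
      st <- filter_sites(st, config$filters)
    }
    state$site_table <- st
    state$pass <- passing_sites(st)
    write_site_table_vcf(st, file.path(config$out_dir, "sites.vcf"))
    write_tsv(st$sites, file.path(config$out_dir, "site_stats.tsv"))
    report$counts$sites_called <<- nrow(st$sites)
    report$counts$sites_passing <<- nrow(state$pass$sites)
  })

  run_stage("windows", function() {
    if (is.null(state$piles) || is.null(state$piles$depth_tracks)) {
      stop("window stage needs simulated depth tracks")
    }
    st <- state$site_table
    dosage <- hard_call(st, config$filters)
    keep <- !st$sites$flag_triallelic & st$sites$n_missing <= config$filters$max_missing
    ref <- stats::setNames(lapply(state$panel$windows, function(w) w$ancestral),
                           state$panel$contigs)
    tracks <- stats::setNames(state$piles$depth_tracks, state$panel$contigs)
    cons <- build_consensus(ref, st$sites[keep, , drop = FALSE],
                            dosage[keep, , drop = FALSE], tracks,
                            depth_min = config$filters$depth_min)
    # each simulated contig is one analysis window
    wins <- lapply(names(cons$seqs), function(ctg) {
      structure(list(contig = ctg, start = 0L,
                     end = cons$contig_lengths[[ctg]],
                     seqs = vapply(cons$seqs[[ctg]], rawToChar, character(1)),
                     completeness = NULL), class = "window_alignment")
    })
    state$windows <- wins
    concat <- concatenate_windows(wins)
    state$concat <- concat
    write_fasta(concat$seqs, file.path(config$out_dir, "concat.fasta"))
    write_bed(concat$map[, c("contig", "start", "end")],
              file.path(config$out_dir, "windows.bed"))
    dm <- p_distance(concat)
    state$dist <- dm
    gens <- divergence_generations(dm, config$divergence)
    write_tsv(as.data.frame(as.table(dm$d)), file.path(config$out_dir, "p_distances.tsv"))
    write_tsv(as.data.frame(as.table(gens)),
              file.path(config$out_dir, "divergence_generations.tsv"))
    write_tsv(as.data.frame(as.table(generations_to_years(gens, config$divergence))),
              file.path(config$out_dir, "divergence_years.tsv"))
    report$counts$windows_retained <<- length(wins)
  })

  run_stage("trees", function() {
    tr_cfg <- config$trees
    if (is.null(tr_cfg)) {
      taxa <- unique(unname(state$pop_map))
      if (length(taxa) >= 5) {
        cnt <- table(state$pop_map)
        island <- names(sort(cnt))[1:2]
        gm <- stats::setNames(ifelse(taxa %in% island, "OUT", taxa), taxa)
        tr_cfg <- list(group_map = gm, outgroup = "OUT")
      } else {
        stop("trees stage needs a trees = list(group_map, outgroup) config with < 5 taxa")
      }
    }
    groups <- stats::setNames(tr_cfg$group_map[state$pop_map], names(state$pop_map))
    trees <- list(); weights <- list()
    for (w in state$windows) {
      dm <- tryCatch(p_distance(w), error = function(e) NULL)
      if (is.null(dm) || anyNA(dm$d)) next
      phy <- nj_tree(dm)
      trees[[length(trees) + 1L]] <- phy
      weights[[length(weights) + 1L]] <-
        topology_weights(phy, groups, tr_cfg$outgroup,
                         seed = subseed(config$seed, 6L, length(weights) + 1L))
    }
    if (!length(weights)) stop("no window produced a defined tree")
    class(trees) <- "multiPhylo"
    ape::write.tree(trees, file.path(config$out_dir, "window_trees.nwk"))
    summ <- weight_summary(weights)
    wtab <- do.call(rbind, lapply(seq_along(weights), function(i) {
      data.frame(window = i, topology = names(weights[[i]]),
                 weight = as.numeric(weights[[i]]))
    }))
    write_tsv(wtab, file.path(config$out_dir, "topology_weights.tsv"))
    write_tsv(summ, file.path(config$out_dir, "topology_summary.tsv"))
    state$weights <- weights
    report$counts$windows_with_trees <<- length(weights)
  })

  run_stage("dstat", function() {
    d_cfg <- config$dstat
    if (is.null(d_cfg)) {
      taxa <- unique(unname(state$pop_map))
      d_cfg <- list(outgroup = taxa[length(taxa)], mode = "population",
                    sisters = taxa[1:2])
    }
    dosage <- hard_call(state$pass, config$filters)
    res <- abba_baba_scan(dosage, state$pop_map, outgroup = d_cfg$outgroup,
                          mode = d_cfg$mode, sisters = d_cfg$sisters,
                          contig = state$pass$sites$contig,
                          pos = state$pass$sites$pos)
    write_tsv(res, file.path(config$out_dir, "dstat.tsv"))
    state$dstat <- res
    report$counts$comparisons_run <<- nrow(res)
  })

  run_stage("fst", function() {
    f_cfg <- config$fst
    taxa <- unique(unname(state$pop_map))
    if (is.null(f_cfg)) f_cfg <- list(pops = taxa[1:2], window = 50000, z_cutoff = 1.15)
    dosage <- hard_call(state$pass, config$filters)
    sites <- wc_fst_sites(dosage, state$pop_map, pops = f_cfg$pops,
                          contig = state$pass$sites$contig,
                          pos = state$pass$sites$pos)
    track <- fst_windows(sites, window = f_cfg$window)
    write_tsv(track, file.path(config$out_dir, "fst_windows.tsv"))
    out <- tryCatch(zscore_outliers(track, z_cutoff = f_cfg$z_cutoff),
                    error = function(e) NULL)
    if (!is.null(out)) {
      write_tsv(out, file.path(config$out_dir, "fst_z.tsv"))
      ol <- out[out$outlier_z, c("contig", "start", "end")]
      write_bed(ol, file.path(config$out_dir, "fst_outliers.bed"))
      report$counts$outliers_found <<- sum(out$outlier_z)
    } else {
      report$counts$outliers_found <<- NA
    }
    state$fst <- track
  })

  run_stage("structure", function() {
    s_cfg <- config$structure_opts
    st <- state$pass
    if (!is.null(s_cfg$thin_bp) && s_cfg$thin_bp > 0) st <- thin_snps(st, s_cfg$thin_bp)
    if (!nrow(st$sites)) stop("no passing sites for structure analysis")
    reps <- replicate_runs(st, K_range = s_cfg$K_range, reps = s_cfg$reps,
                           seed = config$seed)
    write_tsv(reps$table, file.path(config$out_dir, "admixture_likelihoods.tsv"))
    dk <- tryCatch(delta_k(reps), error = function(e) NULL)
    if (!is.null(dk)) {
      write_tsv(dk, file.path(config$out_dir, "delta_k.tsv"))
      report$counts$best_k <<- attr(dk, "best_k")
      bm <- reps$best[[as.character(attr(dk, "best_k"))]]
      if (!is.null(bm)) {
        write_tsv(data.frame(individual = rownames(bm$Q), bm$Q),
                  file.path(config$out_dir, "admixture_Q.tsv"))
      }
    }
    ed <- expected_genotypes(st)
    pca <- gl_pca(ed, freq = st$sites$f_minor)
    write_tsv(data.frame(individual = rownames(pca$coords),
                         pca$coords[, 1:min(4, ncol(pca$coords)), drop = FALSE]),
              file.path(config$out_dir, "pca_coords.tsv"))
    state$pca <- pca
  })

  files <- setdiff(list.files(config$out_dir, full.names = TRUE), character(0))
  files <- files[!grepl("run\\.log$|manifest\\.tsv$|report\\.yaml$", files)]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  report$manifest <- manifest
  report$failed <- failed
  yaml::write_yaml(list(seed = report$seed, version = report$version,
                        counts = report$counts,
                        stages = lapply(report$stages, function(s) s$status)),
                   file.path(config$out_dir, "report.yaml"))
  structure(c(report, list(state = state)), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("museopop run (seed", x$seed, ")\n")
  for (s in names(x$stages)) {
    cat(sprintf("  %-10s %s\n", s, x$stages[[s]]$status))
  }
  for (n in names(x$counts)) cat(sprintf("  %-24s %s\n", n, x$counts[[n]]))
  invisible(x)
}
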