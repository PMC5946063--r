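#' End-to-end pipeline configuration
#'
#' Flat key-value configuration for [run_pipeline()]. Every analysis
#' constant is a named, overridable key; all randomness flows from the
#' single seed through per-stage sub-streams.
#'
#' @param seed master seed.
#' @param outdir output directory (created if needed).
#' @param n_mutants,n_wt_replicates demo screen size when simulating.
#' @param fdr FDR threshold for phenotype and LE calls.
#' @param t_hr fixed outgrowth interpolation time (hours).
#' @param kappa_threshold kappa edge threshold.
#' @param min_cluster minimum cluster size.
#' @param diffusion_d heat-diffusion coefficient.
#' @param plates_path optional existing plate TSV; when `NULL` a screen is
#'   simulated.
#' @param annotations_path optional annotation TSV; when `NULL` annotations
#'   with planted clusters are simulated for the called diet-response
#'   genes.
#' @param network_path optional regulatory-network TSV; when `NULL` a
#'   network with planted regulators is simulated.
#' @param sim further arguments passed to [sim_config()].
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(seed = 1L, outdir = tempfile("chronoscreen_run_"),
                       n_mutants = 200L, n_wt_replicates = 50L,
                       fdr = 0.05, t_hr = 10, kappa_threshold = 0.35,
                       min_cluster = 4L, diffusion_d = 0.25,
                       plates_path = NULL, annotations_path = NULL,
                       network_path = NULL, sim = list()) {
  stopifnot(fdr > 0, fdr < 1, t_hr > 0, kappa_threshold > -1,
            kappa_threshold <= 1, min_cluster >= 1,
            diffusion_d > 0, diffusion_d <= 1)
  structure(list(seed = as.integer(seed), outdir = outdir,
                 n_mutants = as.integer(n_mutants),
                 n_wt_replicates = as.integer(n_wt_replicates),
                 fdr = fdr, t_hr = t_hr,
                 kappa_threshold = kappa_threshold,
                 min_cluster = as.integer(min_cluster),
                 diffusion_d = diffusion_d,
                 plates_path = plates_path,
                 annotations_path = annotations_path,
                 network_path = network_path,
                 sim = sim),
            class = "run_config")
}

#' Run the full screen pipeline: simulate, score, call, LE, cluster, rank
#'
#' Executes the stages in order -- synthetic screen (or a supplied plate
#' file), survival-coefficient scoring, QC, per-condition phenotype calls,
#' lifespan-extension calls, kappa clustering of the diet-response genes,
#' and heat-diffusion TF ranking -- writing one TSV per stage into
#' \code{config$outdir} together with a manifest listing each file and its
#' row count and a run log echoing the configuration. Identical seed and
#' configuration give byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param verbose log stage progress to standard error.
#' @return The manifest data frame (file, rows), invisibly; also written to
#'   \code{manifest.tsv}. The run log is \code{run_log.txt}.
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[chronoscreen] ", ...)
  paths <- character()
  rows <- integer()
  emit <- function(df, name) {
    p <- file.path(config$outdir, name)
    write_result_tsv(as.data.frame(df), p)
    paths[[length(paths) + 1L]] <<- name
    rows[[length(rows) + 1L]] <<- nrow(df)
    p
  }

  # -- stage 1: plates ------------------------------------------------------
  if (is.null(config$plates_path)) {
    say("simulating screen")
    scfg <- do.call(sim_config, c(
      list(seed = config$seed, n_mutants = config$n_mutants,
           n_wt_replicates = config$n_wt_replicates),
      config$sim))
    sim <- simulate_screen(scfg)
    plates <- sim$plates
    truth <- sim$truth
    emit(plates, "plates.tsv")
    emit(truth, "truth.tsv")
  } else {
    if (!file.exists(config$plates_path)) {
      stop("stage plates: input file not found: ", config$plates_path,
           call. = FALSE)
    }
    say("reading plates from ", config$plates_path)
    plates <- read_plate_tsv(config$plates_path)
    truth <- NULL
  }
  conds <- sort(unique(plates$condition))
  if (length(conds) < 2) {
    stop("stage score: need two conditions for the LE analysis, found ",
         length(conds), call. = FALSE)
  }
  cond_nr <- conds[order(conds != "NR")][1]   # prefer explicit NR label
  cond_dr <- setdiff(conds, cond_nr)[1]

  # -- stage 2: score + QC --------------------------------------------------
  say("scoring survival coefficients")
  scores <- score_screen(plates, t_hr = config$t_hr)
  scores <- qc_filter(scores, plates)
  emit(scores, "s_table.tsv")

  wt_ids <- sort(unique(grep("^WT_", scores$strain_id, value = TRUE)))
  if (is.null(truth) || length(wt_ids) == 0) {
    wt_ids <- sort(unique(scores$strain_id[grepl("WT", scores$strain_id)]))
  }
  if (length(wt_ids) < 2) {
    stop("stage call: no WT replicate strains found to build the null",
         call. = FALSE)
  }

  # -- stage 3: per-condition calls -----------------------------------------
  say("calling phenotypes")
  nulls <- list()
  calls <- list()
  for (cond in c(cond_nr, cond_dr)) {
    sc <- scores[scores$condition == cond, , drop = FALSE]
    nulls[[cond]] <- build_null(sc$s[sc$strain_id %in% wt_ids & sc$qc_pass])
    calls[[cond]] <- call_phenotypes(sc, nulls[[cond]], fdr = config$fdr)
  }
  all_calls <- do.call(rbind, lapply(calls, as.data.frame))
  emit(all_calls, "calls.tsv")

  # -- stage 4: LE ----------------------------------------------------------
  say("computing lifespan extension")
  s_nr <- calls[[cond_nr]]
  s_dr <- calls[[cond_dr]]
  shared <- intersect(s_nr$strain_id, s_dr$strain_id)
  le_tab <- data.frame(
    strain_id = shared,
    s_nr = setNames(s_nr$s, s_nr$strain_id)[shared],
    s_dr = setNames(s_dr$s, s_dr$strain_id)[shared],
    stringsAsFactors = FALSE)
  le_tab$le <- compute_le(le_tab$s_nr, le_tab$s_dr)
  wt_le <- wt_le_values(s_nr, s_dr, intersect(wt_ids, shared))
  le_null <- build_null(wt_le)
  le_calls <- call_le(le_tab[!le_tab$strain_id %in% wt_ids, , drop = FALSE],
                      le_null, s_nr, s_dr, fdr = config$fdr)
  emit(le_calls, "le.tsv")

  dr_genes <- le_calls$strain_id[le_calls$class != "ns"]

  # -- stage 5: kappa clustering --------------------------------------------
  say("clustering ", length(dr_genes), " diet-response genes")
  if (!is.null(config$annotations_path)) {
    if (!file.exists(config$annotations_path)) {
      stop("stage cluster: input file not found: ", config$annotations_path,
           call. = FALSE)
    }
    annot <- read_annotation_tsv(config$annotations_path)
  } else {
    n_genes <- max(length(dr_genes), 8L)
    planted <- if (n_genes >= 12) c(6L, 5L) else integer()
    annot <- simulate_annotations(
      n_genes = n_genes, n_terms = 1748, planted_clusters = planted,
      seed = config$seed + 31L)
    rn <- rownames(annot)
    rn[seq_len(min(length(dr_genes), n_genes))] <-
      head(dr_genes, n_genes)
    rownames(annot) <- rn
  }
  keep <- intersect(rownames(annot), dr_genes)
  annot_use <- if (length(keep) >= 2) annot[keep, , drop = FALSE] else annot
  edges <- build_kappa_network(annot_use, threshold = config$kappa_threshold)
  clusters <- merge_clusters(edges, min_size = config$min_cluster)
  le_vec <- setNames(le_calls$le, le_calls$strain_id)
  export_cluster_network(edges, clusters,
                         prefix = file.path(config$outdir, "clusters"),
                         le = le_vec)
  for (nm in c("clusters.sif", "clusters_edges.tsv", "clusters_nodes.tsv")) {
    paths[[length(paths) + 1L]] <- nm
    rows[[length(rows) + 1L]] <-
      length(readLines(file.path(config$outdir, nm))) -
      as.integer(nm != "clusters.sif")
  }

  # -- stage 6: TF ranking --------------------------------------------------
  say("ranking transcription factors")
  if (!is.null(config$network_path)) {
    if (!file.exists(config$network_path)) {
      stop("stage rank-tfs: input file not found: ", config$network_path,
           call. = FALSE)
    }
    net <- read_network_tsv(config$network_path)
    targets <- dr_genes
  } else {
    reg <- simulate_regnet(n_tfs = 40, n_genes = max(length(dr_genes), 50L),
                           target_set_size = max(length(dr_genes), 10L),
                           seed = config$seed + 77L)
    net <- reg$network
    targets <- reg$targets
  }
  tf_ranks <- rank_tfs(net, targets, d = config$diffusion_d)
  emit(tf_ranks, "tf_ranks.tsv")

  manifest <- data.frame(file = unlist(paths), rows = unlist(rows),
                         stringsAsFactors = FALSE)
  write_result_tsv(manifest, file.path(config$outdir, "manifest.tsv"))

  log_lines <- c(
    "chronoscreen run log",
    paste0("seed=", config$seed),
    paste0("fdr=", config$fdr),
    paste0("t_hr=", config$t_hr),
    paste0("kappa_threshold=", config$kappa_threshold),
    paste0("min_cluster=", config$min_cluster),
    paste0("diffusion_d=", config$diffusion_d),
    paste0("n_mutants=", config$n_mutants),
    paste0("n_wt_replicates=", config$n_wt_replicates),
    paste0("conditions=", paste(conds, collapse = ",")),
    paste0("dr_genes=", length(dr_genes)),
    "files:",
    paste0("  ", manifest$file, "\t", manifest$rows, " rows"))
  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
  say("done: ", nrow(manifest), " output files in ", config$outdir)
  invisible(manifest)
}
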