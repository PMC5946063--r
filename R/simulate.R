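#' Draw a synthetic strain panel with ground-truth death rates
#'
#' Generates the strain table for a synthetic screen: \code{n_wt_replicates}
#' wild-type replicate co-cultures sharing the reference death rates, plus
#' \code{n_mutants} deletion strains whose per-condition death rates are
#' drawn from a three-component mixture: 80\% "neutral" strains scattered
#' tightly around the wild-type rate (sd 0.005/day), 10\% short-lived
#' (rate increased by 0.03--0.10/day) and 10\% long-lived (rate decreased by
#' 0.01--0.025/day), truncated at zero. Effect sizes are drawn independently
#' per condition, so mutants naturally differ in their diet response.
#'
#' @param config a [sim_config()].
#' @return A data frame of class \code{"strain_panel"} with one row per
#'   strain: \code{strain_id}, \code{is_wt}, \code{class} (ground-truth
#'   phenotype class: \code{"wt"}, \code{"neutral"}, \code{"short"},
#'   \code{"long"}), one \code{death_rate_<cond>} column per condition, and
#'   \code{growth_rate} (per hour).
#' @export
#' @examples
#' panel <- simulate_panel(sim_config(seed = 7, n_mutants = 5,
#'                                    n_wt_replicates = 3))
#' panel$class
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  conds <- names(config$death_rate_wt)
  n_wt <- config$n_wt_replicates
  n_mut <- config$n_mutants

  wt_ids <- sprintf("WT_%03d", seq_len(n_wt))
  mut_ids <- if (n_mut > 0) sprintf("MUT_%04d", seq_len(n_mut)) else character()

  cls <- if (n_mut > 0) {
    sample(c("neutral", "short", "long"), n_mut, replace = TRUE,
           prob = c(0.8, 0.1, 0.1))
  } else character()

  rates <- matrix(NA_real_, nrow = n_wt + n_mut, ncol = length(conds),
                  dimnames = list(NULL, paste0("death_rate_", tolower(conds))))
  for (j in seq_along(conds)) {
    r_wt <- config$death_rate_wt[[j]]
    rates[seq_len(n_wt), j] <- r_wt
    if (n_mut > 0) {
      r <- numeric(n_mut)
      r[cls == "neutral"] <- r_wt + rnorm(sum(cls == "neutral"), 0, 0.005)
      r[cls == "short"] <- r_wt + runif(sum(cls == "short"), 0.03, 0.10)
      r[cls == "long"] <- r_wt - runif(sum(cls == "long"), 0.01, 0.025)
      rates[n_wt + seq_len(n_mut), j] <- pmax(r, 0)
    }
  }

  # doubling times: WT fixed; mutants scattered within the viable range
  dt_mut <- pmin(pmax(rnorm(n_mut, 3.0, 0.4), 1.6), 5.5)
  growth <- log(2) / c(rep(config$doubling_time_wt_hr, n_wt), dt_mut)

  panel <- data.frame(
    strain_id = c(wt_ids, mut_ids),
    is_wt = c(rep(TRUE, n_wt), rep(FALSE, n_mut)),
    class = c(rep("wt", n_wt), cls),
    stringsAsFactors = FALSE
  )
  panel <- cbind(panel, as.data.frame(rates))
  panel$growth_rate <- growth
  class(panel) <- c("strain_panel", "data.frame")
  panel
}

# Vectorised generative core shared by simulate_competition() and
# simulate_screen(). Viable inocula decay exponentially with age; each
# subpopulation regrows exponentially at its own rate and the total is
# saturated hyperbolically towards the carrying capacity, preserving the
# RFP:CFP ratio exactly (both channels see the same saturation factor).
sim_curves_core <- function(ids, r_mut, g_mut, r_ref, g_ref, well_delta,
                            condition, config) {
  ages <- config$ages_days
  times <- config$outgrowth_times_hr
  n_s <- length(ids)
  n_a <- length(ages)
  n_t <- length(times)

  idx_s <- rep(seq_len(n_s), each = n_a * n_t)
  age <- rep(rep(ages, each = n_t), times = n_s)
  tt <- rep(times, times = n_s * n_a)

  r_m <- (r_mut + well_delta)[idx_s]
  g_m <- g_mut[idx_s]

  vm0 <- config$inoculum_od * config$mix_ratio / (1 + config$mix_ratio)
  vr0 <- config$inoculum_od / (1 + config$mix_ratio)

  pm <- vm0 * exp(-pmax(r_m, 0) * age + g_m * tt)
  pr <- vr0 * exp(-r_ref * age + g_ref * tt)
  tot <- pm + pr
  k <- config$carrying_capacity
  sat <- k / (k + tot)          # common saturation factor, ratio-preserving
  pm_s <- pm * sat
  pr_s <- pr * sat

  n <- length(pm_s)
  if (config$noise_cv > 0) {
    sl <- sqrt(log(1 + config$noise_cv^2))
    f_r <- rlnorm(n, meanlog = -sl^2 / 2, sdlog = sl)
    f_c <- rlnorm(n, meanlog = -sl^2 / 2, sdlog = sl)
  } else {
    f_r <- f_c <- rep(1, n)
  }
  rfp <- config$fl_scale_rfp * pm_s * f_r
  cfp <- config$fl_scale_cfp * pr_s * f_c

  out_r <- out_c <- rep(FALSE, n)
  if (config$outlier_rate > 0) {
    out_r <- runif(n) < config$outlier_rate
    out_c <- runif(n) < config$outlier_rate
    if (any(out_r)) {
      rfp[out_r] <- rfp[out_r] *
        sample(c(10, 0.1), sum(out_r), replace = TRUE)
    }
    if (any(out_c)) {
      cfp[out_c] <- cfp[out_c] *
        sample(c(10, 0.1), sum(out_c), replace = TRUE)
    }
  }

  od <- (pm_s + pr_s) + config$od_baseline
  if (config$od_sd > 0) od <- pmax(od + rnorm(n, 0, config$od_sd), 0)

  plates <- data.frame(
    strain_id = ids[idx_s],
    condition = condition,
    age_days = age,
    time_hr = tt,
    od600 = od,
    rfp = rfp,
    cfp = cfp,
    stringsAsFactors = FALSE
  )
  any_out <- out_r | out_c
  outliers <- data.frame(
    strain_id = ids[idx_s][any_out],
    condition = rep(condition, sum(any_out)),
    age_days = age[any_out],
    time_hr = tt[any_out],
    channel = ifelse(out_r[any_out], "rfp", "cfp"),
    stringsAsFactors = FALSE
  )
  list(plates = plates, outliers = outliers)
}

#' Simulate one competitive co-culture across stationary-phase ages
#'
#' Ages a mutant:reference co-culture and simulates one outgrowth per
#' stationary-phase age. Viable fractions decay as \eqn{e^{-r \cdot age}};
#' during outgrowth each subpopulation grows exponentially from its viable
#' inoculum at its own growth rate, with a shared hyperbolic saturation
#' towards the carrying capacity. RFP tracks the mutant, CFP the reference;
#' fluorescence noise is multiplicative lognormal with occasional gross
#' outliers, and OD600 is the population sum plus baseline and additive
#' noise.
#'
#' @param mutant,reference one-row subsets of a [simulate_panel()] panel
#'   (or lists with the same fields).
#' @param config a [sim_config()].
#' @param condition which condition's death-rate column to use.
#' @param seed optional seed for this single competition.
#' @return A long-format data frame of readings (\code{strain_id},
#'   \code{condition}, \code{age_days}, \code{time_hr}, \code{od600},
#'   \code{rfp}, \code{cfp}) with an \code{"outliers"} attribute flagging
#'   corrupted readings and a \code{"well_delta"} attribute giving the
#'   realized well effect.
#' @export
simulate_competition <- function(mutant, reference, config,
                                 condition = names(config$death_rate_wt)[1],
                                 seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!condition %in% names(config$death_rate_wt)) {
    stop("unknown condition: ", condition, call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  col <- paste0("death_rate_", tolower(condition))
  r_mut <- as.numeric(mutant[[col]])
  r_ref <- as.numeric(reference[[col]])
  stopifnot(is.finite(r_mut), is.finite(r_ref))
  wd <- if (config$well_sd > 0) rnorm(1, 0, config$well_sd) else 0
  res <- sim_curves_core(
    ids = as.character(mutant$strain_id),
    r_mut = r_mut, g_mut = as.numeric(mutant$growth_rate),
    r_ref = r_ref, g_ref = as.numeric(reference$growth_rate),
    well_delta = wd, condition = condition, config = config
  )
  structure(res$plates, outliers = res$outliers, well_delta = wd)
}

#' Simulate a full competitive CLS screen with ground truth
#'
#' Runs [simulate_panel()] and simulates every strain (mutants and WT
#' replicate co-cultures) against the wild-type reference under each
#' condition. Each co-culture receives an independent well effect (a small
#' Gaussian perturbation of its realized death-rate difference, shared
#' machinery for WT replicates and mutants) so that the WT-vs-WT null
#' captures the experimental variance a mutant experiences.
#'
#' @param config a [sim_config()].
#' @param conditions conditions to simulate (default: all in the config).
#' @param panel optional pre-built \code{"strain_panel"} (e.g. with
#'   hand-chosen ground-truth rates); defaults to [simulate_panel()].
#' @return A list of class \code{"cls_screen_sim"}:
#'   \describe{
#'     \item{plates}{long-format readings for all strains and conditions;}
#'     \item{truth}{the panel plus, per condition, the realized well effect
#'       (\code{well_delta_<cond>}) and the intended true survival
#'       coefficient \code{true_s_<cond>} \eqn{= r_{ref} - r_{mut}};}
#'     \item{outliers}{ground-truth locations of corrupted readings.}
#'   }
#' @export
#' @examples
#' sim <- simulate_screen(sim_config(seed = 1, n_mutants = 4,
#'                                   n_wt_replicates = 3))
#' head(sim$plates)
simulate_screen <- function(config,
                            conditions = names(config$death_rate_wt),
                            panel = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(panel)) panel <- simulate_panel(config)
  plates <- vector("list", length(conditions))
  outs <- vector("list", length(conditions))
  truth <- panel
  for (i in seq_along(conditions)) {
    cond <- conditions[i]
    col <- paste0("death_rate_", tolower(cond))
    if (is.null(panel[[col]])) stop("unknown condition: ", cond, call. = FALSE)
    # independent, reproducible sub-stream per condition
    set.seed(config$seed + 1000L * i)
    wd <- if (config$well_sd > 0) {
      rnorm(nrow(panel), 0, config$well_sd)
    } else rep(0, nrow(panel))
    res <- sim_curves_core(
      ids = panel$strain_id,
      r_mut = panel[[col]], g_mut = panel$growth_rate,
      r_ref = config$death_rate_wt[[cond]],
      g_ref = log(2) / config$doubling_time_wt_hr,
      well_delta = wd, condition = cond, config = config
    )
    plates[[i]] <- res$plates
    outs[[i]] <- res$outliers
    truth[[paste0("well_delta_", tolower(cond))]] <- wd
    truth[[paste0("true_s_", tolower(cond))]] <-
      config$death_rate_wt[[cond]] - panel[[col]]
  }
  structure(list(
    plates = do.call(rbind, plates),
    truth = truth,
    outliers = do.call(rbind, outs)
  ), class = "cls_screen_sim")
}

#' @export
print.cls_screen_sim <- function(x, ...) {
  cat("Synthetic CLS screen:", length(unique(x$truth$strain_id)), "strains,",
      length(unique(x$plates$condition)), "condition(s),",
      nrow(x$plates), "plate readings\n")
  invisible(x)
}

#' Simulate a binary gene-by-term annotation matrix with planted clusters
#'
#' Background genes receive independent Bernoulli(\code{p_background}) term
#' associations, so their pairwise chance-corrected agreement is zero in
#' expectation. Each planted cluster is assigned a disjoint block of
#' \code{signature_terms} signature terms that its members carry with
#' probability \code{p_signature}, which puts within-cluster Cohen's kappa
#' well above the usual 0.35 clustering threshold by construction.
#'
#' @param n_genes,n_terms matrix dimensions.
#' @param planted_clusters integer vector of planted cluster sizes (may be
#'   empty). Members are assigned from the first genes, disjointly.
#' @param seed integer seed.
#' @param p_background background association probability.
#' @param signature_terms number of signature terms per planted cluster.
#' @param p_signature probability that a member carries a signature term.
#' @return A binary matrix (genes x terms, dimnames set) with attribute
#'   \code{"planted"}: a list of member-id character vectors.
#' @export
#' @examples
#' m <- simulate_annotations(20, 200, planted_clusters = c(5), seed = 1)
#' attr(m, "planted")
simulate_annotations <- function(n_genes, n_terms, planted_clusters = integer(),
                                 seed = 1L, p_background = 0.03,
                                 signature_terms = 80, p_signature = 0.95) {
  stopifnot(n_genes >= 1, n_terms >= 1)
  planted_clusters <- as.integer(planted_clusters)
  if (sum(planted_clusters) > n_genes) {
    stop("planted cluster members exceed `n_genes`", call. = FALSE)
  }
  if (length(planted_clusters) * signature_terms > n_terms) {
    stop("not enough terms for disjoint cluster signatures", call. = FALSE)
  }
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  terms <- sprintf("T%04d", seq_len(n_terms))
  m <- matrix(rbinom(n_genes * n_terms, 1, p_background),
              nrow = n_genes, dimnames = list(genes, terms))
  planted <- list()
  g0 <- 0
  for (k in seq_along(planted_clusters)) {
    size <- planted_clusters[k]
    members <- genes[g0 + seq_len(size)]
    sig <- (k - 1) * signature_terms + seq_len(signature_terms)
    m[members, sig] <- rbinom(size * signature_terms, 1, p_signature)
    planted[[k]] <- members
    g0 <- g0 + size
  }
  attr(m, "planted") <- planted
  m
}

#' Simulate a directed regulatory network with planted regulators
#'
#' Builds a TF-to-gene edge list in which "planted" regulators send many
#' direct and indirect (via intermediate TFs) edges into a designated target
#' gene set, while decoy TFs regulate only genes outside it. Serves as
#' ground truth for heat-diffusion regulator ranking.
#'
#' @param n_tfs,n_genes numbers of transcription factors and genes.
#' @param target_set_size size of the target gene set.
#' @param seed integer seed.
#' @param n_planted number of planted regulators (default ~10\% of TFs).
#' @param p_direct probability a planted TF directly regulates each target.
#' @param p_indirect probability a planted TF feeds each intermediate TF
#'   that itself regulates targets.
#' @param out_degree typical number of non-target genes a decoy regulates.
#' @return A list: \code{network} (a data frame of class
#'   \code{"reg_network"} with columns \code{regulator}, \code{target} and
#'   a \code{"tfs"} attribute), \code{targets}, \code{planted},
#'   \code{decoys}.
#' @export
simulate_regnet <- function(n_tfs, n_genes, target_set_size, seed = 1L,
                            n_planted = max(1L, round(0.1 * n_tfs)),
                            p_direct = 0.4, p_indirect = 0.2,
                            out_degree = 8) {
  stopifnot(n_tfs >= 2, n_genes >= 2, target_set_size >= 1,
            target_set_size <= n_genes, n_planted < n_tfs)
  set.seed(seed)
  tfs <- sprintf("TF%03d", seq_len(n_tfs))
  genes <- sprintf("G%04d", seq_len(n_genes))
  targets <- genes[seq_len(target_set_size)]
  nontargets <- setdiff(genes, targets)
  planted <- tfs[seq_len(n_planted)]
  inter_n <- min(max(2L, round(0.2 * n_tfs)), n_tfs - n_planted)
  intermediates <- tfs[n_planted + seq_len(inter_n)]
  decoys <- setdiff(tfs, c(planted, intermediates))

  edge <- function(from, to) {
    if (length(to) == 0) return(NULL)
    data.frame(regulator = from, target = to, stringsAsFactors = FALSE)
  }
  edges <- list()
  for (tf in planted) {
    hit <- targets[runif(length(targets)) < p_direct]
    edges[[length(edges) + 1L]] <- edge(tf, hit)
    via <- intermediates[runif(length(intermediates)) < p_indirect]
    edges[[length(edges) + 1L]] <- edge(tf, via)
  }
  for (tf in intermediates) {
    hit <- targets[runif(length(targets)) < p_direct / 2]
    edges[[length(edges) + 1L]] <- edge(tf, hit)
  }
  for (tf in decoys) {
    k <- min(length(nontargets), max(1L, rbinom(1, 2 * out_degree, 0.5)))
    edges[[length(edges) + 1L]] <- edge(tf, sample(nontargets, k))
  }
  net <- do.call(rbind, edges)
  net <- unique(net)
  net <- net[net$regulator != net$target, , drop = FALSE]
  rownames(net) <- NULL
  net <- structure(net, tfs = tfs, class = c("reg_network", "data.frame"))
  list(network = net, targets = targets, planted = planted, decoys = decoys)
}
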