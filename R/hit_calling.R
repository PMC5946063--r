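#' Build an empirical wild-type null distribution
#'
#' Summarises the statistic (survival coefficient \eqn{s} in one condition,
#' or the lifespan-extension LE) over wild-type replicate co-cultures into
#' the mean and standard deviation used for mutant Z-scores, assuming the
#' mutants share the wild-type variance.
#'
#' @param wt_values numeric vector of the WT statistic (length >= 2).
#' @return Object of class \code{"wt_null"}: \code{mu}, \code{sigma},
#'   \code{n}.
#' @export
#' @examples
#' build_null(c(-0.01, 0, 0.01))   # mu 0, sigma 0.01
build_null <- function(wt_values) {
  wt_values <- wt_values[is.finite(wt_values)]
  if (length(wt_values) < 2) {
    stop("need >= 2 finite WT values to build a null", call. = FALSE)
  }
  sigma <- sd(wt_values)
  if (sigma <= 0) {
    stop("degenerate WT null: zero standard deviation", call. = FALSE)
  }
  structure(list(mu = mean(wt_values), sigma = sigma, n = length(wt_values)),
            class = "wt_null")
}

#' @export
print.wt_null <- function(x, digits = 4, ...) {
  cat("WT null: mu =", format(x$mu, digits = digits),
      ", sigma =", format(x$sigma, digits = digits),
      " (n =", x$n, "replicates)\n")
  invisible(x)
}

# Benjamini-Hochberg step-up: reject the i smallest p with
# p_(i) <= i/m * alpha for the largest such i
bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ok <- p[o] <= seq_len(m) / m * alpha
  k <- if (any(ok)) max(which(ok)) else 0L
  rej <- logical(m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

#' Call CLS phenotypes against the wild-type null
#'
#' Assigns each qc-passing strain a Z-score \eqn{(s - \mu_{wt})/\sigma_{wt}},
#' a two-tailed normal p-value, and a Benjamini-Hochberg adjusted q-value
#' computed within each condition. Strains with \code{q <= fdr} are called
#' \code{short_lived} (s below the null mean) or \code{long_lived} (above);
#' all others are \code{neutral}.
#'
#' @param scores a \code{"cls_scores"} table ([score_screen()]); only rows
#'   with \code{qc_pass} are tested.
#' @param null a \code{"wt_null"} for \eqn{s}, or a named list of nulls
#'   (one per condition) when `scores` spans several conditions.
#' @param fdr FDR threshold.
#' @return `scores` rows that passed QC, with added \code{z}, \code{p},
#'   \code{q} and \code{call} columns; class \code{"phenotype_calls"}.
#' @export
call_phenotypes <- function(scores, null, fdr = 0.05) {
  stopifnot(fdr > 0, fdr < 1)
  df <- as.data.frame(scores)[scores$qc_pass, , drop = FALSE]
  if (nrow(df) == 0) stop("no qc-passing strains to call", call. = FALSE)
  conds <- unique(df$condition)
  get_null <- function(cond) {
    nl <- if (inherits(null, "wt_null")) null else null[[cond]]
    if (is.null(nl)) stop("no null supplied for condition ", cond,
                          call. = FALSE)
    if (nl$sigma <= 0) stop("null sigma must be > 0", call. = FALSE)
    nl
  }
  df$z <- NA_real_
  df$p <- NA_real_
  df$q <- NA_real_
  for (cond in conds) {
    i <- df$condition == cond
    nl <- get_null(cond)
    z <- (df$s[i] - nl$mu) / nl$sigma
    p <- 2 * pnorm(-abs(z))
    df$z[i] <- z
    df$p[i] <- p
    df$q[i] <- p.adjust(p, method = "BH")   # step-up within condition
  }
  # step-up rule applied directly on p (p_(i) <= i/m * fdr), per condition;
  # equivalent to q <= fdr but numerically exact at the boundary
  df$reject <- FALSE
  for (cond in conds) {
    i <- which(df$condition == cond)
    df$reject[i] <- bh_reject(df$p[i], fdr)
  }
  df$call <- ifelse(!df$reject, "neutral",
                    ifelse(df$z < 0, "short_lived", "long_lived"))
  df$reject <- NULL
  rownames(df) <- NULL
  class(df) <- c("phenotype_calls", "data.frame")
  df
}

#' Lifespan-extension statistic
#'
#' \eqn{LE = (s_{DR} + 1) / (s_{NR} + 1)}: the ratio of a strain's
#' one-plus-survival-coefficient under dietary restriction to that under
#' the non-restricted diet. \eqn{LE = 1} means the diet changed nothing;
#' \eqn{LE < 1} a diminished and \eqn{LE > 1} an enhanced response relative
#' to wild type. Undefined (returned as \code{NA} with a warning) when
#' \eqn{s_{NR} \le -1}.
#'
#' @param s_nr,s_dr survival coefficients in the non-restricted and
#'   restricted condition (vectorised).
#' @return Numeric LE values.
#' @export
#' @examples
#' compute_le(0, -0.1)     # 0.9
#' compute_le(-0.5, 0)     # 2.0
compute_le <- function(s_nr, s_dr) {
  stopifnot(length(s_nr) == length(s_dr))
  bad <- !is.na(s_nr) & s_nr <= -1
  if (any(bad)) {
    warning(sum(bad), " strain(s) with s_NR <= -1: LE undefined, set NA",
            call. = FALSE)
  }
  le <- (s_dr + 1) / (s_nr + 1)
  le[bad] <- NA_real_
  le
}

#' Call lifespan-extension classes with the stringency filter
#'
#' Scores each strain's LE against the wild-type LE null (Z, two-tailed p,
#' Benjamini-Hochberg q across all tested strains), then applies the
#' stringency filter: strains whose LE is significant but that are neutral
#' under both single-condition calls are demoted to \code{ns}. Survivors
#' are classed \code{diminished} (LE < 1) or \code{enhanced} (LE > 1), and
#' given a joint category string "LE class | NR call | DR call".
#'
#' @param le_table data frame with \code{strain_id} and \code{le}.
#' @param wt_le_null a \code{"wt_null"} built from WT replicate LE values
#'   (see [wt_le_values()]).
#' @param calls_nr,calls_dr \code{"phenotype_calls"} tables for the two
#'   conditions; strains missing from either are excluded with a warning.
#' @param fdr FDR threshold.
#' @return Data frame of class \code{"le_calls"} with \code{z}, \code{p},
#'   \code{q}, \code{class} and \code{category} columns.
#' @export
call_le <- function(le_table, wt_le_null, calls_nr, calls_dr, fdr = 0.05) {
  stopifnot(inherits(wt_le_null, "wt_null"), fdr > 0, fdr < 1)
  df <- as.data.frame(le_table)
  stopifnot(all(c("strain_id", "le") %in% names(df)))
  nr <- setNames(calls_nr$call, calls_nr$strain_id)
  dr <- setNames(calls_dr$call, calls_dr$strain_id)
  present <- df$strain_id %in% names(nr) & df$strain_id %in% names(dr) &
    !is.na(df$le)
  if (any(!present)) {
    warning(sum(!present),
            " strain(s) excluded from LE calling (missing condition call ",
            "or undefined LE)", call. = FALSE)
    df <- df[present, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no strains left to call LE on", call. = FALSE)
  df$z <- (df$le - wt_le_null$mu) / wt_le_null$sigma
  df$p <- 2 * pnorm(-abs(df$z))
  df$q <- p.adjust(df$p, method = "BH")   # once across all strains
  df$call_nr <- unname(nr[df$strain_id])
  df$call_dr <- unname(dr[df$strain_id])
  sig <- bh_reject(df$p, fdr)
  # stringency: a significant LE without any single-condition phenotype is ns
  both_neutral <- df$call_nr == "neutral" & df$call_dr == "neutral"
  df$class <- ifelse(!sig | both_neutral, "ns",
                     ifelse(df$le < 1, "diminished", "enhanced"))
  df$category <- paste(df$class, df$call_nr, df$call_dr, sep = " | ")
  rownames(df) <- NULL
  class(df) <- c("le_calls", "data.frame")
  df
}

#' Wild-type LE null values by replicate pairing
#'
#' Builds the per-replicate wild-type LE values by pairing WT replicate
#' \eqn{i} in the non-restricted screen with WT replicate \eqn{i} in the
#' restricted screen (plate-position pairing, the default) or by random
#' pairing.
#'
#' @param scores_nr,scores_dr score tables for the two conditions.
#' @param wt_ids character vector of WT replicate strain ids.
#' @param pairing \code{"position"} (match by id) or \code{"random"}.
#' @param seed seed used for random pairing.
#' @return Numeric vector of WT LE values.
#' @export
wt_le_values <- function(scores_nr, scores_dr, wt_ids,
                         pairing = c("position", "random"), seed = 1L) {
  pairing <- match.arg(pairing)
  s_nr <- setNames(scores_nr$s, scores_nr$strain_id)[wt_ids]
  s_dr <- setNames(scores_dr$s, scores_dr$strain_id)[wt_ids]
  if (pairing == "random") {
    set.seed(seed)
    s_dr <- sample(s_dr)
  }
  compute_le(unname(s_nr), unname(s_dr))
}

#' Recompute LE against an alternative reference screen and test skew
#'
#' Recomputes the lifespan-extension values of all strains using an
#' alternative non-restricted screen as the denominator, then tests by a
#' one-tailed Wilcoxon rank-sum test whether a designated gene set's LE
#' values skew below (default) or above those of the remaining strains.
#'
#' @param scores_dr score table (restricted condition), columns
#'   \code{strain_id}, \code{s}.
#' @param scores_alt alternative non-restricted score table.
#' @param gene_set designated strain ids (non-empty).
#' @param alternative \code{"less"} (set skews below the rest) or
#'   \code{"greater"}.
#' @return List: \code{le} (data frame of strain_id, le_alt),
#'   \code{p_value}, \code{statistic}, \code{n_set}, \code{n_rest}.
#' @export
cross_reference_le <- function(scores_dr, scores_alt, gene_set,
                               alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(gene_set) == 0) stop("empty designated gene set", call. = FALSE)
  shared <- intersect(scores_dr$strain_id, scores_alt$strain_id)
  if (length(shared) < 10) {
    stop("fewer than 10 shared strains between screens", call. = FALSE)
  }
  s_dr <- setNames(scores_dr$s, scores_dr$strain_id)[shared]
  s_alt <- setNames(scores_alt$s, scores_alt$strain_id)[shared]
  le_alt <- compute_le(unname(s_alt), unname(s_dr))
  names(le_alt) <- shared
  in_set <- shared %in% gene_set
  if (!any(in_set)) {
    stop("designated gene set shares no strains with the screens",
         call. = FALSE)
  }
  wt <- wilcox.test(le_alt[in_set], le_alt[!in_set],
                    alternative = alternative, exact = FALSE)
  list(le = data.frame(strain_id = shared, le_alt = unname(le_alt),
                       in_set = in_set, stringsAsFactors = FALSE),
       p_value = wt$p.value, statistic = unname(wt$statistic),
       n_set = sum(in_set), n_rest = sum(!in_set))
}
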