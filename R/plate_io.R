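#' Read a long-format plate-reader TSV
#'
#' The plate schema is tab-separated with a header row and one reading per
#' row: \code{strain_id}, \code{condition}, \code{age_days}, \code{time_hr},
#' \code{od600}, \code{rfp}, \code{cfp}. Rows are grouped into one outgrowth
#' curve per (strain, condition, age) and time-sorted; missing readings are
#' simply absent rows. Malformed numeric cells are rejected with the line
#' number and column named.
#'
#' @param path file path.
#' @return A data frame of class \code{"plate_data"} sorted by strain,
#'   condition, age and time.
#' @export
read_plate_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", check.names = FALSE)
  required <- c("strain_id", "condition", "age_days", "time_hr",
                "od600", "rfp", "cfp")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("plate TSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- c("age_days", "time_hr", "od600", "rfp", "cfp")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad) > 0) {
      stop("non-numeric value in column '", col, "' at data line ",
           bad[1] + 1L, ": '", df[[col]][bad[1]], "'", call. = FALSE)
    }
    df[[col]] <- v
  }
  if (any(df$od600 < 0, na.rm = TRUE)) {
    stop("negative od600 readings are not allowed", call. = FALSE)
  }
  if (any(df$age_days < 0, na.rm = TRUE)) {
    stop("negative ages are not allowed", call. = FALSE)
  }
  df <- df[order(df$strain_id, df$condition, df$age_days, df$time_hr), ,
           drop = FALSE]
  dup <- duplicated(df[c("strain_id", "condition", "age_days", "time_hr")])
  if (any(dup)) {
    stop("duplicate readings for the same strain/condition/age/time",
         call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("plate_data", "data.frame")
  df
}

#' Write a plate-reader TSV
#'
#' @param plates a data frame with the plate schema columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @rdname read_plate_tsv
#' @export
write_plate_tsv <- function(plates, path) {
  cols <- c("strain_id", "condition", "age_days", "time_hr",
            "od600", "rfp", "cfp")
  stopifnot(all(cols %in% names(plates)))
  write.table(format(plates[cols], digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split plate data into single outgrowth curves
#'
#' @param plates a \code{"plate_data"} data frame.
#' @return A list of \code{"outgrowth_curve"} data frames (columns
#'   \code{time_hr}, \code{od600}, \code{rfp}, \code{cfp}; attributes
#'   \code{strain_id}, \code{condition}, \code{age_days}), one per
#'   (strain, condition, age).
#' @export
split_curves <- function(plates) {
  key <- interaction(plates$strain_id, plates$condition, plates$age_days,
                     drop = TRUE, lex.order = TRUE)
  lapply(split(seq_len(nrow(plates)), key), function(i) {
    sub <- plates[i, , drop = FALSE]
    sub <- sub[order(sub$time_hr), , drop = FALSE]
    outgrowth_curve(sub$time_hr, sub$od600, sub$rfp, sub$cfp,
                    strain_id = sub$strain_id[1],
                    condition = sub$condition[1],
                    age_days = sub$age_days[1])
  })
}

#' Construct a single outgrowth curve
#'
#' @param time_hr,od600,rfp,cfp numeric reading vectors, equal length.
#' @param strain_id,condition,age_days curve identity.
#' @return A data frame of class \code{"outgrowth_curve"}.
#' @export
outgrowth_curve <- function(time_hr, od600, rfp = NA_real_, cfp = NA_real_,
                            strain_id = NA_character_,
                            condition = NA_character_, age_days = NA_real_) {
  n <- length(time_hr)
  stopifnot(n >= 1, length(od600) == n)
  if (length(rfp) == 1) rfp <- rep(rfp, n)
  if (length(cfp) == 1) cfp <- rep(cfp, n)
  if (any(diff(time_hr) <= 0)) {
    stop("curve times must be strictly increasing", call. = FALSE)
  }
  if (any(od600 < 0, na.rm = TRUE)) {
    stop("od600 must be non-negative", call. = FALSE)
  }
  structure(
    data.frame(time_hr = time_hr, od600 = od600, rfp = rfp, cfp = cfp),
    strain_id = strain_id, condition = condition, age_days = age_days,
    class = c("outgrowth_curve", "data.frame")
  )
}

#' Read / write a binary gene-by-term annotation matrix
#'
#' The annotation TSV has genes in the first column (header \code{gene}) and
#' one column per term; entries must be 0 or 1. Duplicate gene or term
#' identifiers are rejected.
#'
#' @param path file path.
#' @return A binary matrix with gene rownames and term colnames.
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  if (names(df)[1] != "gene") {
    stop("annotation TSV must have 'gene' as its first column",
         call. = FALSE)
  }
  genes <- df$gene
  terms <- names(df)[-1]
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifier(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(terms)) {
    stop("duplicate term identifier(s): ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (length(m) > 0 && !all(m %in% c("0", "1"))) {
    bad <- setdiff(unique(as.vector(m)), c("0", "1"))
    stop("annotation entries must be 0 or 1; found: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(genes, terms)
  m
}

#' @param m binary matrix (genes x terms) with dimnames.
#' @rdname read_annotation_tsv
#' @export
write_annotation_tsv <- function(m, path) {
  stopifnot(is.matrix(m))
  df <- data.frame(gene = rownames(m), as.data.frame(m, optional = TRUE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a directed regulatory network edge list
#'
#' Two tab-separated columns, \code{regulator} and \code{target}; every
#' regulator is flagged as a transcription factor. Duplicate edges and
#' self-loops are rejected.
#'
#' @param path file path.
#' @return A data frame of class \code{"reg_network"} with attribute
#'   \code{"tfs"} (the regulator set).
#' @export
read_network_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", check.names = FALSE)
  if (!all(c("regulator", "target") %in% names(df))) {
    stop("network TSV must have 'regulator' and 'target' columns",
         call. = FALSE)
  }
  df <- df[c("regulator", "target")]
  if (any(df$regulator == df$target)) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  if (anyDuplicated(df)) {
    stop("duplicate edges in network file", call. = FALSE)
  }
  structure(df, tfs = sort(unique(df$regulator)),
            class = c("reg_network", "data.frame"))
}

#' @param network a \code{"reg_network"} data frame.
#' @rdname read_network_tsv
#' @export
write_network_tsv <- function(network, path) {
  stopifnot(all(c("regulator", "target") %in% names(network)))
  write.table(as.data.frame(network)[c("regulator", "target")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Generic writer for all result tables (survival coefficients, phenotype
#' calls, lifespan-extension tables, decay fits, TF ranks); plain
#' tab-separated text with a header, stable column order.
#'
#' @param df a data frame.
#' @param path output path.
#' @export
write_result_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_tsv
#' @export
read_result_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
}
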