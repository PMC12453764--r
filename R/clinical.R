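#' Fit a clinical feature encoder
#'
#' Learns standardisation and one-hot state on a training table only, so
#' that validation/test records are transformed without leakage. Continuous
#' features get mean/sd with the population convention (divide by n) plus the
#' training median for imputation; constant columns are dropped with a
#' warning. Categorical features get lexicographically sorted vocabularies;
#' missing values become an explicit \code{"missing"} category.
#'
#' The output layout is deterministic: continuous features first, then the
#' one-hot blocks, each group in alphabetical order.
#'
#' @param table data.frame of clinical records (>= 2 rows).
#' @param continuous character names of continuous columns; default
#'   \code{c("age", "symptom_duration")}.
#' @param categorical character names of categorical columns; default
#'   \code{c("gender", "history_flag", "skin_type")}.
#' @return a \linkS4class{ClinicalEncoder}.
#' @examples
#' tab <- data.frame(age = c(20, 40, 60), symptom_duration = c(5, 10, 30),
#'                   gender = c("F", "M", "F"), history_flag = c(0, 1, 0),
#'                   skin_type = c("II", "III", "II"))
#' enc <- fitClinicalEncoder(tab)
#' transformClinical(tab, enc)
#' @export
fitClinicalEncoder <- function(table,
                               continuous = c("age", "symptom_duration"),
                               categorical = c("gender", "history_flag", "skin_type")) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("a non-empty training table is required")
  if (nrow(table) < 2L) stop("at least 2 rows required to fit an encoder")
  missing_cols <- setdiff(c(continuous, categorical), colnames(table))
  if (length(missing_cols))
    stop(sprintf("columns absent from table: %s", paste(missing_cols, collapse = ", ")))

  continuous <- sort(continuous)
  categorical <- sort(categorical)

  cont <- list(); dropped <- character(0)
  for (nm in continuous) {
    x <- as.numeric(table[[nm]])
    med <- stats::median(x, na.rm = TRUE)
    x[is.na(x)] <- med
    if (!all(is.finite(x))) stop(sprintf("non-finite values in '%s'", nm))
    mu <- mean(x)
    sdev <- sqrt(mean((x - mu)^2))  # population convention
    if (sdev <= 0 || length(unique(x)) < 2L) {
      warning(sprintf("constant continuous column '%s' dropped", nm))
      dropped <- c(dropped, nm)
    } else {
      cont[[nm]] <- list(mean = mu, sd = sdev, median = med)
    }
  }

  cats <- list()
  for (nm in categorical) {
    x <- as.character(table[[nm]])
    x[is.na(x) | x == ""] <- "missing"
    cats[[nm]] <- sort(unique(x))
  }

  fn <- c(names(cont),
          unlist(lapply(names(cats), function(nm)
            paste(nm, cats[[nm]], sep = "=")), use.names = FALSE))
  methods::new("ClinicalEncoder", continuous = cont, categorical = cats,
               dropped = dropped, featureNames = as.character(fn))
}

#' Transform clinical records into feature vectors
#'
#' Applies the fitted encoder: continuous values map to z-scores
#' \code{(x - mu) / sigma} (NAs imputed with the training median);
#' categorical values map to one-hot vectors in vocabulary order. An unseen
#' category raises an error naming the column and value. Output columns
#' follow the fitted layout, so each one-hot block sums to exactly 1 per row.
#'
#' @param table data.frame of records to transform.
#' @param encoder a fitted \linkS4class{ClinicalEncoder}.
#' @return numeric matrix, one row per record, columns =
#'   \code{featureNames(encoder)}.
#' @export
transformClinical <- function(table, encoder) {
  stopifnot(is(encoder, "ClinicalEncoder"))
  n <- nrow(table)
  out <- matrix(0, n, length(encoder@featureNames),
                dimnames = list(NULL, encoder@featureNames))
  for (nm in names(encoder@continuous)) {
    if (!nm %in% colnames(table)) stop(sprintf("column '%s' missing", nm))
    el <- encoder@continuous[[nm]]
    x <- as.numeric(table[[nm]])
    x[is.na(x)] <- el$median
    out[, nm] <- (x - el$mean) / el$sd
  }
  for (nm in names(encoder@categorical)) {
    if (!nm %in% colnames(table)) stop(sprintf("column '%s' missing", nm))
    vocab <- encoder@categorical[[nm]]
    x <- as.character(table[[nm]])
    x[is.na(x) | x == ""] <- "missing"
    bad <- setdiff(unique(x), vocab)
    if (length(bad))
      stop(sprintf("unseen category in column '%s': %s", nm,
                   paste(bad, collapse = ", ")))
    for (v in vocab)
      out[, paste(nm, v, sep = "=")] <- as.numeric(x == v)
  }
  out
}

#' Persist a fitted encoder as JSON
#'
#' @param encoder a \linkS4class{ClinicalEncoder}.
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writeEncoder <- function(encoder, file) {
  stopifnot(is(encoder, "ClinicalEncoder"))
  jsonlite::write_json(list(continuous = encoder@continuous,
                            categorical = encoder@categorical,
                            dropped = encoder@dropped,
                            featureNames = encoder@featureNames),
                       file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Load an encoder written by \code{\link{writeEncoder}}
#'
#' @param file JSON path.
#' @return a \linkS4class{ClinicalEncoder}.
#' @export
readEncoder <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  cont <- lapply(x$continuous, as.list)
  methods::new("ClinicalEncoder", continuous = cont,
               categorical = as.list(x$categorical),
               dropped = as.character(x$dropped %||% character(0)),
               featureNames = as.character(x$featureNames))
}
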