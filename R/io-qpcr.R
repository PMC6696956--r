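QPCR_TARGETS <- c("vnp1_attB", "vnp2_attB", "vnp1_circle", "vnp2_circle",
                  "reference_tk", "standard", "delta_junction")

#' qPCR plate
#'
#' Long-format plate: one row per well, with sample id, amplification
#' target, threshold cycle, known concentration (standards only) and
#' technical-replicate index. A missing `ct` (`NA`) is the
#' no-amplification sentinel, not a Ct of 40.
#'
#' @param df data frame with columns `sample_id`, `target`, `ct` and
#'   optionally `known_conc`, `replicate`.
#' @return An object of classes `qpcr_plate` and `data.frame`.
#' @export
qpcr_plate <- function(df) {
  req <- c("sample_id", "target", "ct")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop2("missing column(s): ", paste(miss, collapse = ", "))
  if (!"known_conc" %in% names(df)) df$known_conc <- NA_real_
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  df$sample_id <- as.character(df$sample_id)
  df$target <- as.character(df$target)
  df$ct <- as.numeric(df$ct)
  df$known_conc <- as.numeric(df$known_conc)
  df$replicate <- as.integer(df$replicate)
  bad_t <- setdiff(unique(df$target), QPCR_TARGETS)
  if (length(bad_t)) stop2("unknown target(s): ", paste(bad_t, collapse = ", "))
  if (any(!is.na(df$ct) & df$ct <= 0)) stop2("Ct values must be positive")
  std <- df$target == "standard"
  if (any(std & is.na(df$known_conc))) {
    stop2("standard wells must carry known_conc")
  }
  structure(df, class = c("qpcr_plate", "data.frame"))
}

#' Read a qPCR plate from CSV
#'
#' Comma-separated with a mandatory header. Required columns: `sample_id`,
#' `target`, `ct`; optional: `known_conc`, `replicate`. Replicate wells are
#' preserved as rows, never averaged at read time.
#'
#' @param path path to the CSV file.
#' @return A [qpcr_plate()].
#' @export
read_qpcr_csv <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  qpcr_plate(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a qPCR plate to CSV
#'
#' @param plate a [qpcr_plate()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qpcr_csv <- function(plate, path) {
  stopifnot(inherits(plate, "qpcr_plate"))
  utils::write.csv(as.data.frame(plate), path, row.names = FALSE)
  invisible(path)
}

#' Split a plate into standard and unknown wells
#'
#' @param plate a [qpcr_plate()].
#' @return For `plate_standards`, the rows with target `"standard"`;
#'   for `plate_unknowns`, all other rows.
#' @export
plate_standards <- function(plate) {
  as.data.frame(plate)[plate$target == "standard", , drop = FALSE]
}

#' @rdname plate_standards
#' @export
plate_unknowns <- function(plate) {
  as.data.frame(plate)[plate$target != "standard", , drop = FALSE]
}
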