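#' Read a cohort manifest
#'
#' The manifest is a CSV with (at least) the columns `slide_id`,
#' `class_label`, `centre`, `split`, `path`; unknown columns are preserved.
#' Validation errors name the offending rows.
#'
#' @param path CSV file path.
#' @return a `cohort_manifest` data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  if (file.size(path) == 0)
    stop("empty manifest file (no header): ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_manifest(df, where = path)
}

validate_manifest <- function(df, where = "manifest") {
  required <- c("slide_id", "class_label", "centre", "split", "path")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(where, " is missing column(s): ", paste(missing, collapse = ", "))
  dup <- unique(df$slide_id[duplicated(df$slide_id)])
  if (length(dup) > 0)
    stop(where, " has duplicate slide_id(s): ", paste(dup, collapse = ", "))
  bad_label <- df$slide_id[!df$class_label %in% c("A", "B", "OOD")]
  if (length(bad_label) > 0)
    stop(where, " has unknown class_label for slide(s): ",
         paste(bad_label, collapse = ", "))
  bad_split <- df$slide_id[!df$split %in% c("train", "val", "test")]
  if (length(bad_split) > 0)
    stop(where, " has unknown split for slide(s): ",
         paste(bad_split, collapse = ", "))
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Write a cohort manifest
#'
#' @param manifest a `cohort_manifest` (or conforming data frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- validate_manifest(as.data.frame(manifest))
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
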