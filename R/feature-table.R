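FT_KINDS <- c("asv_counts", "absolute_abundance", "genus_abundance",
              "metabolite_concentration", "clr_values")

#' Construct a feature table
#'
#' The universal matrix carrier of the package: features (ASVs, genera or
#' metabolites) in rows, samples in columns, plus a `kind` tag that records
#' what the values are (raw counts, 16S copies per sample, concentrations in
#' assay units, or CLR-transformed values).
#'
#' Values must be finite and non-negative, except that `clr_values` may be
#' negative and `metabolite_concentration` may contain `NA` for missing
#' cells (imputed later by [condition_metabolites()]).
#'
#' @param values numeric matrix with unique rownames (feature ids) and unique
#'   colnames (sample ids).
#' @param kind one of `"asv_counts"`, `"absolute_abundance"`,
#'   `"genus_abundance"`, `"metabolite_concentration"`, `"clr_values"`.
#' @return A `feature_table` object (a matrix with a `kind` attribute).
#' @export
feature_table <- function(values, kind = FT_KINDS) {
  kind <- match.arg(kind, FT_KINDS)
  if (!is.matrix(values) || !is.numeric(values))
    stop_mm("`values` must be a numeric matrix")
  fid <- rownames(values); sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop_mm("feature_table requires rownames (features) and colnames (samples)")
  if (anyDuplicated(fid))
    stop_mm("duplicate feature ids: ", paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop_mm("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (anyNA(values) && kind != "metabolite_concentration")
    stop_mm("missing values are only permitted in metabolite_concentration tables")
  finite_ok <- is.finite(values) | is.na(values)
  if (!all(finite_ok)) stop_mm("feature_table values must be finite")
  if (kind != "clr_values" && any(values < 0, na.rm = TRUE))
    stop_mm("negative values are only permitted in clr_values tables")
  structure(values, kind = kind, class = c("feature_table", "matrix", "array"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table [%s]: %d features x %d samples\n",
              ft_kind(x), nrow(x), ncol(x)))
  invisible(x)
}

#' Kind tag of a feature table
#' @param x a [feature_table()].
#' @return Character scalar kind tag.
#' @export
ft_kind <- function(x) attr(x, "kind") %||% NA_character_

#' @export
`[.feature_table` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out)) out <- structure(out, kind = attr(x, "kind"),
                                       class = class(x))
  out
}

ft_values <- function(x) {
  out <- unclass(x)
  attr(out, "kind") <- NULL
  out
}

# align a feature table to a sample order (must be a subset of its samples)
ft_align <- function(x, sample_ids) {
  missing <- setdiff(sample_ids, colnames(x))
  if (length(missing))
    stop_mm("samples absent from table: ", paste(missing, collapse = ", "))
  x[, sample_ids, drop = FALSE]
}
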