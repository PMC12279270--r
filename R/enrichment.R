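#' Over-representation analysis of a metabolite set
#'
#' For each pathway with at least one member in the background: with
#' `N = |background|`, `K` pathway members in the background, `n = |query|`
#' and `k` observed hits, the upper-tail hypergeometric p-value
#' `P(X >= k)`, the expected hit count `n K / N`, and the enrichment ratio
#' `observed / expected`. Benjamini-Hochberg correction is applied across
#' all tested pathways; rows are sorted by p then pathway name. Pathways
#' with no background member are skipped (and reported).
#'
#' @param query metabolite identifier set (character); must be a subset of
#'   `background`.
#' @param background the measured, library-mappable metabolite universe.
#' @param library a `pathway_library` (see [read_gmt()]).
#' @param invert_ratio report expected/observed instead (off by default;
#'   the conventional direction is observed/expected).
#' @return Data frame: `pathway_id`, `pathway_name`, `background_size`,
#'   `pathway_size`, `observed_hits`, `expected_hits`, `enrichment_ratio`,
#'   `p`, `q`, with attribute `skipped` (pathway ids with K = 0).
#' @export
ora <- function(query, background, library, invert_ratio = FALSE) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  bad <- setdiff(query, background)
  if (length(bad))
    stop_mm("query metabolites absent from background: ",
            paste(bad, collapse = ", "))
  out <- data.frame(pathway_id = character(), pathway_name = character(),
                    background_size = integer(), pathway_size = integer(),
                    observed_hits = integer(), expected_hits = double(),
                    enrichment_ratio = double(), p = double(), q = double(),
                    stringsAsFactors = FALSE)
  if (!length(query)) return(structure(out, skipped = character()))
  N <- length(background); n <- length(query)
  skipped <- character()
  rows <- list()
  for (s in library) {
    members <- intersect(s$members, background)
    K <- length(members)
    if (K == 0) { skipped <- c(skipped, s$id); next }
    k <- length(intersect(members, query))
    expected <- n * K / N
    rows[[s$id]] <- data.frame(
      pathway_id = s$id, pathway_name = s$name,
      background_size = N, pathway_size = K, observed_hits = k,
      expected_hits = expected,
      enrichment_ratio = if (invert_ratio) {
        if (k == 0) Inf else expected / k
      } else k / expected,
      p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    message("ora: skipped pathways with no background member: ",
            paste(skipped, collapse = ", "))
  if (!length(rows)) {
    if (!length(library)) stop_mm("empty pathway library")
    stop_mm("background shares no metabolite with the library")
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$pathway_name), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, skipped = skipped)
}
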