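# Gene-set over-representation by the one-sided Fisher exact
# (hypergeometric) test, and comparison of the term sets produced by the
# restrictive and integrative feature lists.

#' Gene-set over-representation analysis
#'
#' One-sided (over-representation) hypergeometric test of each gene set
#' against a selected feature list within a measured universe. Sets are
#' intersected with the universe first; sets whose intersection has
#' fewer than 2 members are skipped. P-values are BH-adjusted across the
#' tested sets and the table is sorted by p.
#'
#' @param selected character vector of selected features; must be a
#'   subset of \code{universe}.
#' @param universe all features tested in the corresponding analysis
#'   stage.
#' @param sets named list of character vectors (e.g. from
#'   \code{\link{readGMT}}).
#' @return data.frame: set_name, overlap, set_size, selected_size,
#'   universe_size, odds_ratio, p, bh_adjusted_p, description.
#' @examples
#' u <- paste0("g", 1:100)
#' fisherEnrich(u[1:10], u, list(s = u[1:20]))
#' @export
fisherEnrich <- function(selected, universe, sets) {
    if (!length(universe)) stop("empty universe")
    universe <- unique(universe)
    selected <- unique(selected)
    if (length(setdiff(selected, universe)))
        stop("selected features must be a subset of the universe")
    M <- length(universe)
    nsel <- length(selected)
    rows <- lapply(names(sets), function(nm) {
        s <- intersect(sets[[nm]], universe)
        K <- length(s)
        if (K < 2L) return(NULL)
        k <- length(intersect(selected, s))
        p <- stats::phyper(k - 1, K, M - K, nsel, lower.tail = FALSE)
        orat <- (k * (M - K - nsel + k)) / ((K - k) * (nsel - k))
        d <- attr(sets[[nm]], "description")
        data.frame(set_name = nm, overlap = k, set_size = K,
                   selected_size = nsel, universe_size = M,
                   odds_ratio = orat, p = p,
                   description = if (is.null(d)) NA_character_ else d,
                   stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows))
        return(data.frame(set_name = character(), overlap = integer(),
                          set_size = integer(), selected_size = integer(),
                          universe_size = integer(),
                          odds_ratio = numeric(), p = numeric(),
                          bh_adjusted_p = numeric(),
                          description = character(),
                          stringsAsFactors = FALSE))
    rows$bh_adjusted_p <- stats::p.adjust(rows$p, "BH")
    rows <- rows[order(rows$p, rows$set_name),
                 c("set_name", "overlap", "set_size", "selected_size",
                   "universe_size", "odds_ratio", "p", "bh_adjusted_p",
                   "description")]
    rownames(rows) <- NULL
    rows
}

#' Compare enriched term sets from two feature lists
#'
#' @param termsRestrictive,termsIntegrative character vectors of
#'   significant set names obtained at the same threshold from the
#'   restrictive and the integrative feature lists.
#' @return list with \code{n_restrictive}, \code{n_integrative},
#'   \code{n_common} and \code{common} (the intersection, sorted).
#' @export
compareTermSets <- function(termsRestrictive, termsIntegrative) {
    common <- sort(intersect(termsRestrictive, termsIntegrative))
    list(n_restrictive = length(unique(termsRestrictive)),
         n_integrative = length(unique(termsIntegrative)),
         n_common = length(common),
         common = common)
}
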