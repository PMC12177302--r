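#' Gene-set overlap test with representation factor
#'
#' Tests whether two gene sets drawn from a common universe overlap more than
#' expected under independence. The expected overlap is `n1 * n2 / N`, the
#' representation factor is `observed / expected`, and the enrichment
#' p-value is `P(X >= observed)` for `X` hypergeometric with parameters
#' `(N, n1, n2)`. For universes larger than `approx_threshold` a normal
#' approximation with continuity correction is used and recorded in `method`.
#'
#' @param set1,set2 Character vectors of identifiers, subsets of `universe`.
#' @param universe Character vector: the identifier universe (e.g. all
#'   expressed genes). Must be supplied explicitly.
#' @param approx_threshold Universe size beyond which the normal
#'   approximation is used (default 1e6, i.e. effectively always exact).
#' @param alternative `"enrichment"` (default) for `P(X >= observed)` or
#'   `"depletion"` for `P(X <= observed)`.
#' @return An [OverlapResult-class].
#' @export
overlapTest <- function(set1, set2, universe, approx_threshold = 1e6,
                        alternative = c("enrichment", "depletion")) {
  alternative <- match.arg(alternative)
  set1 <- unique(set1)
  set2 <- unique(set2)
  universe <- unique(universe)
  out1 <- setdiff(set1, universe)
  out2 <- setdiff(set2, universe)
  if (length(out1) || length(out2)) {
    stop("element(s) outside the universe: ",
         paste(head(c(out1, out2), 5), collapse = ", "), call. = FALSE)
  }
  n1 <- length(set1); n2 <- length(set2); N <- length(universe)
  observed <- length(intersect(set1, set2))
  # double precision: the variance product overflows integer arithmetic
  expected <- as.numeric(n1) * n2 / N
  rf <- if (expected > 0) observed / expected else NA_real_

  if (N <= approx_threshold) {
    method <- "exact"
    p <- if (alternative == "enrichment") {
      phyper(observed - 1, n1, N - n1, n2, lower.tail = FALSE)
    } else {
      phyper(observed, n1, N - n1, n2)
    }
  } else {
    method <- "normal_approx"
    v <- as.numeric(n1) * n2 * (N - n1) * (N - n2) / (as.numeric(N)^2 * (N - 1))
    p <- if (alternative == "enrichment") {
      pnorm((observed - 0.5 - expected) / sqrt(v), lower.tail = FALSE)
    } else {
      pnorm((observed + 0.5 - expected) / sqrt(v))
    }
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  methods::new("OverlapResult", n1 = as.integer(n1), n2 = as.integer(n2),
               N = as.integer(N), observed = as.integer(observed),
               expected = expected,
               representation_factor = if (is.na(rf)) NA_real_ else rf,
               p_value = p, method = method)
}

#' Exclusive region counts for 2- or 3-set Venn comparisons
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return data.frame with `region` (e.g. `"A"`, `"A&B"`) and `count`; the
#'   counts sum to the size of the union.
#' @export
vennCounts <- function(sets) {
  k <- length(sets)
  if (!k %in% c(2L, 3L)) stop("vennCounts expects 2 or 3 sets", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- LETTERS[seq_len(k)]
  }
  sets <- lapply(sets, unique)
  all_ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 1L) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(r) {
    paste(names(sets)[r], collapse = "&")
  })
  combos <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(names(sets), m, FUN = paste, collapse = "&")
  }))
  counts <- table(factor(pattern, levels = combos))
  data.frame(region = combos, count = as.integer(counts),
             stringsAsFactors = FALSE)
}
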