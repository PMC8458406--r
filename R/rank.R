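# Frobenius norm of every zero-sum-gauge coupling block (L x L symmetric).
.frobenius_scores <- function(model) {
  if (model$gauge != "zero_sum") model <- to_zero_sum_gauge(model)
  L <- model$L; q <- model$q
  fn <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    ri <- ((i - 1L) * q + 1L):(i * q)
    for (j in (i + 1L):L) {
      rj <- ((j - 1L) * q + 1L):(j * q)
      fn[i, j] <- fn[j, i] <- sqrt(sum(model$J[ri, rj]^2))
    }
  }
  fn
}

# Average-product correction: S_ij = F_ij - F_i. F_.j / F..
.apply_apc <- function(fn) {
  L <- nrow(fn)
  rowm <- rowSums(fn) / (L - 1)
  allm <- sum(fn) / (L * (L - 1))
  corr <- fn - outer(rowm, rowm) / allm
  diag(corr) <- 0
  corr
}

# Direct information of one pair: mutual information of the two-site
# distribution P(A,B) proportional to exp(e_ij(A,B)) x(A) y(B), with x, y
# fitted so the marginals match f_i, f_j (iterative proportional fitting).
.direct_information <- function(eij, fi, fj, tol = 1e-8, max_iter = 1000L) {
  W <- exp(eij)
  x <- rep(1, length(fi)); y <- rep(1, length(fj))
  for (it in seq_len(max_iter)) {
    x_new <- fi / as.vector(W %*% y)
    y_new <- fj / as.vector(crossprod(W, x_new))
    if (max(abs(x_new - x), abs(y_new - y)) < tol) { x <- x_new; y <- y_new; break }
    x <- x_new; y <- y_new
  }
  P <- outer(x, y) * W
  P <- P / sum(P)
  ref <- outer(fi, fj)
  sum(P * log(P / ref))
}

#' Rank coevolving residue pairs of a fitted Potts model
#'
#' Scores every candidate column pair either by direct information (DI: the
#' mutual information of the two-site distribution induced by the pair's
#' direct coupling and marginals matching the single-site frequencies) or by
#' the average-product-corrected Frobenius norm of the zero-sum-gauge
#' coupling block. The top-ranked inter-module pairs define the support of
#' the compatibility score C(S); the field convention truncates to the top
#' 1500 pairs for the LacI family.
#'
#' @param model A \code{"potts_model"} (any gauge; converted internally) or
#'   an \code{"mfdca_fit"}.
#' @param freqs A \code{"freq_model"} sharing L and q (only the single-site
#'   frequencies are used; may be omitted when \code{model} is a fit).
#' @param metric \code{"direct_information"} (default) or \code{"frobenius_apc"}.
#' @param restrict_to Optional two-column matrix/data.frame of candidate
#'   pairs (e.g. from \code{\link{inter_module_pairs}}); otherwise all pairs.
#' @param top_k Optional truncation after ranking (e.g. 1500).
#' @return Object of class \code{"pair_scores"}: data.frame with columns
#'   \code{i}, \code{j} (i < j), \code{score}, sorted descending with ties
#'   broken by (i, j) lexicographic order; attribute \code{metric}.
#' @export
rank_pairs <- function(model, freqs = NULL,
                       metric = c("direct_information", "frobenius_apc"),
                       restrict_to = NULL, top_k = NULL) {
  metric <- match.arg(metric)
  if (inherits(model, "mfdca_fit")) {
    if (is.null(freqs)) freqs <- model$freqs
    model <- model$model
  }
  stopifnot(inherits(model, "potts_model"))
  if (metric == "direct_information") {
    if (is.null(freqs)) stop("direct information requires the frequency model",
                             call. = FALSE)
    stopifnot(inherits(freqs, "freq_model"))
    if (freqs$L != model$L || freqs$q != model$q) {
      stop("model and frequencies disagree on L or q", call. = FALSE)
    }
  }
  L <- model$L
  if (is.null(restrict_to)) {
    restrict_to <- t(utils::combn(L, 2L))
  } else {
    restrict_to <- as.matrix(restrict_to)[, 1:2, drop = FALSE]
  }
  ii <- pmin(restrict_to[, 1L], restrict_to[, 2L])
  jj <- pmax(restrict_to[, 1L], restrict_to[, 2L])
  if (any(ii == jj)) stop("self-pairs are not rankable", call. = FALSE)
  keep <- !duplicated(cbind(ii, jj))
  ii <- ii[keep]; jj <- jj[keep]

  if (metric == "frobenius_apc") {
    sc_full <- .apply_apc(.frobenius_scores(model))
    score <- sc_full[cbind(ii, jj)]
  } else {
    score <- vapply(seq_along(ii), function(k) {
      .direct_information(coupling_block(model, ii[k], jj[k]),
                          freqs$fi[ii[k], ], freqs$fi[jj[k], ])
    }, 0)
  }
  if (any(!is.finite(score))) stop("non-finite pair scores", call. = FALSE)
  ord <- order(-score, ii, jj)
  out <- data.frame(i = ii[ord], j = jj[ord], score = score[ord])
  if (!is.null(top_k)) out <- out[seq_len(min(top_k, nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, metric = metric, class = c("pair_scores", "data.frame"))
}

#' All inter-module (DBM x LBM) column pairs of a partition
#' @param partition A \code{\link{module_partition}}.
#' @return Two-column matrix of pairs (unordered, one row each).
#' @export
inter_module_pairs <- function(partition) {
  stopifnot(inherits(partition, "module_partition"))
  as.matrix(expand.grid(i = partition$dbm_columns, j = partition$lbm_columns,
                        KEEP.OUT.ATTRS = FALSE))
}

#' Write ranked pairs as TSV (1-based columns: i, j, score, metric)
#' @param pairs A \code{"pair_scores"} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  df <- as.data.frame(pairs)
  df$metric <- attr(pairs, "metric")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
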