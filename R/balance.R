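# SMOTE class balancing.
#
# Synthetic minority oversampling: each synthetic row is a convex
# combination x + delta * (x' - x) of a minority row x and one of its k
# nearest minority neighbours x' (Euclidean distance, one shared delta ~
# U(0, 1) per synthetic row). Enough synthetics are generated to equalise
# all class counts with the majority class. Balancing must only ever see
# training rows; the cross-validation driver enforces this.

#' SMOTE oversampling to equal class counts
#'
#' @param x numeric feature matrix or data.frame (training rows only).
#' @param y class labels.
#' @param k nearest minority neighbours to sample from (default 5);
#'   reduced, with a warning, when a minority class has at most k members.
#' @param seed integer seed; the result is deterministic given the seed.
#' @return object of class `balanced_table`: `x` (original rows first, then
#'   synthetics), `y`, and `provenance` (per-row `origin` flag plus
#'   `parent1`/`parent2` row indices into the input for synthetic rows).
#' @export
smote <- function(x, y, k = 5L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.character(y)
  n <- nrow(x)
  if (n != length(y)) stop("x and y sizes differ")
  cnt <- table(y)
  n_maj <- max(cnt)
  prov <- data.frame(origin = rep("original", n), parent1 = NA_integer_,
                     parent2 = NA_integer_, stringsAsFactors = FALSE)
  syn_x <- list(); syn_y <- character(0)
  with_seed(seed, {
    for (cl in names(cnt)[cnt < n_maj]) {
      n_c <- cnt[[cl]]
      if (n_c < 2)
        stop("minority class '", cl, "' has a single sample; ",
             "SMOTE needs at least 2")
      kk <- min(k, n_c - 1)
      if (kk < k)
        warning("k reduced to ", kk, " for minority class '", cl, "'")
      idx <- which(y == cl)
      xc <- x[idx, , drop = FALSE]
      dmat <- as.matrix(stats::dist(xc))
      need <- n_maj - n_c
      base <- rep(seq_len(n_c), length.out = need)
      for (s in seq_len(need)) {
        i <- base[s]
        others <- setdiff(seq_len(n_c), i)
        nb <- others[order(dmat[i, others], others)][seq_len(kk)]
        j <- nb[sample.int(kk, 1)]
        delta <- stats::runif(1)
        syn_x[[length(syn_x) + 1]] <- x[idx[i], ] +
          delta * (x[idx[j], ] - x[idx[i], ])
        syn_y <- c(syn_y, cl)
        prov <- rbind(prov, data.frame(origin = "synthetic",
                                       parent1 = idx[i], parent2 = idx[j],
                                       stringsAsFactors = FALSE))
      }
    }
  })
  out_x <- if (length(syn_x) > 0) rbind(x, do.call(rbind, syn_x)) else x
  rownames(out_x) <- NULL
  structure(list(x = out_x, y = c(y, syn_y), provenance = prov),
            class = "balanced_table")
}

#' @export
print.balanced_table <- function(x, ...) {
  cat(sprintf("<balanced_table: %d rows (%d synthetic), classes %s>\n",
              nrow(x$x), sum(x$provenance$origin == "synthetic"),
              paste(sprintf("%s=%d", names(table(x$y)), table(x$y)),
                    collapse = ", ")))
  invisible(x)
}
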