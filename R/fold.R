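# Minimum free energy secondary-structure folding.
#
# Dynamic program over all nested (pseudoknot-free) structures with a
# minimum hairpin loop of 3 unpaired bases.  The energy of a structure is
# the sum of nearest-neighbor stacking terms over adjacent pairs (see
# energy.R); isolated pairs contribute 0.  Because positive G.U-on-G.U
# stacks exist in the table, the recursion keeps two matrices: V(i,j) is
# the optimum given that (i,j) pairs, W(i,j) the unconstrained optimum.
# The stacked case must be separated from the generic interior case so
# that the (possibly unfavourable) stacking term is always charged when
# (i+1,j-1) also pairs.
#
# Ties are broken deterministically: fewer pairs first, then the option
# generated first in a fixed enumeration order (skip, stack, 5'-most
# branch), so the traceback is reproducible.

.FOLD_EPS <- 1e-9

#' Fold a sequence into its minimum free energy secondary structure
#'
#' @param seq nucleotide string (A/C/G/U/T), length 1..200.
#' @param min_loop minimum number of unpaired bases in a hairpin loop.
#' @return a list of class \code{fold_result} with elements
#'   \code{structure} (dot-bracket string), \code{mfe} (kcal/mol, <= 0)
#'   and \code{pairs} (integer vector of partner positions, 0 = unpaired).
#' @export
fold_mfe <- function(seq, min_loop = 3L) {
  codes <- seq_to_codes(seq)
  n <- length(codes)
  if (n < 1L || n > 200L) stop("sequence length must be in [1, 200]")
  empty <- list(structure = strrep(".", n), mfe = 0,
                pairs = integer(n))
  class(empty) <- "fold_result"
  if (n < min_loop + 2L) return(empty)

  P <- matrix(.PAIR_INDEX[codes, ][, codes], n, n)
  V <- matrix(Inf, n, n)   # optimum with (i,j) paired
  NV <- matrix(0L, n, n)   # pair count of that optimum
  W <- matrix(0, n, n)     # unconstrained optimum
  NW <- matrix(0L, n, n)

  gW <- function(i, j) if (i > j) 0 else W[i, j]
  gNW <- function(i, j) if (i > j) 0L else NW[i, j]

  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      ## --- V(i, j): (i, j) forms a pair ------------------------------
      if (P[i, j] > 0L) {
        # option a: i+1 unpaired inside; any structure on [i+2, j-1]
        e <- gW(i + 2L, j - 1L)
        np <- gNW(i + 2L, j - 1L)
        # option b: stack on (i+1, j-1)
        if (j - i >= min_loop + 3L && P[i + 1L, j - 1L] > 0L &&
            is.finite(V[i + 1L, j - 1L])) {
          es <- .STACK_ENERGY[P[i, j], P[i + 1L, j - 1L]] + V[i + 1L, j - 1L]
          ns <- NV[i + 1L, j - 1L]
          if (es < e - .FOLD_EPS || (es < e + .FOLD_EPS && ns < np)) {
            e <- es; np <- ns
          }
        }
        # option c: i+1 paired with k < j-1 (excludes the stacked case)
        ks <- if (i + 1L + min_loop + 1L <= j - 2L)
          (i + min_loop + 2L):(j - 2L) else integer(0)
        if (length(ks)) {
          ks <- ks[is.finite(V[i + 1L, ks])]
          if (length(ks)) {
            wr <- ifelse(ks + 1L > j - 1L, 0, W[cbind(ks + 1L, j - 1L)])
            nr <- ifelse(ks + 1L > j - 1L, 0L, NW[cbind(ks + 1L, j - 1L)])
            ev <- V[i + 1L, ks] + wr
            nv <- NV[i + 1L, ks] + nr
            bm <- min(ev)
            if (bm < e + .FOLD_EPS) {
              cand <- which(ev < bm + .FOLD_EPS)
              pick <- cand[which.min(nv[cand])]
              if (bm < e - .FOLD_EPS ||
                  (bm < e + .FOLD_EPS && nv[pick] < np)) {
                e <- ev[pick]; np <- nv[pick]
              }
            }
          }
        }
        V[i, j] <- e
        NV[i, j] <- np + 1L
      }
      ## --- W(i, j): unconstrained ------------------------------------
      e <- W[i + 1L, j]
      np <- NW[i + 1L, j]
      ks <- (i + min_loop + 1L):j
      ks <- ks[is.finite(V[i, ks])]
      if (length(ks)) {
        wr <- ifelse(ks + 1L > j, 0, W[cbind(pmin(ks + 1L, j), j)])
        wr[ks + 1L > j] <- 0
        nr <- integer(length(ks))
        inr <- ks + 1L <= j
        nr[inr] <- NW[cbind(ks[inr] + 1L, j)]
        ev <- V[i, ks] + wr
        nv <- NV[i, ks] + nr
        bm <- min(ev)
        if (bm < e + .FOLD_EPS) {
          cand <- which(ev < bm + .FOLD_EPS)
          pick <- cand[which.min(nv[cand])]
          if (bm < e - .FOLD_EPS || (bm < e + .FOLD_EPS && nv[pick] < np)) {
            e <- ev[pick]; np <- nv[pick]
          }
        }
      }
      W[i, j] <- e
      NW[i, j] <- np
    }
  }

  ## ----- traceback ---------------------------------------------------
  pairs <- integer(n)
  tb_V <- function(i, j) {
    pairs[i] <<- j; pairs[j] <<- i
    target <- V[i, j]; ntarget <- NV[i, j] - 1L
    # option a
    if (abs(gW(i + 2L, j - 1L) - target) < .FOLD_EPS &&
        gNW(i + 2L, j - 1L) == ntarget) {
      if (i + 2L <= j - 1L) tb_W(i + 2L, j - 1L)
      return(invisible())
    }
    # option b: stack
    if (j - i >= min_loop + 3L && P[i + 1L, j - 1L] > 0L &&
        is.finite(V[i + 1L, j - 1L])) {
      es <- .STACK_ENERGY[P[i, j], P[i + 1L, j - 1L]] + V[i + 1L, j - 1L]
      if (abs(es - target) < .FOLD_EPS && NV[i + 1L, j - 1L] == ntarget) {
        tb_V(i + 1L, j - 1L)
        return(invisible())
      }
    }
    # option c
    ks <- if (i + 1L + min_loop + 1L <= j - 2L)
      (i + min_loop + 2L):(j - 2L) else integer(0)
    for (k in ks) {
      if (!is.finite(V[i + 1L, k])) next
      wr <- gW(k + 1L, j - 1L); nr <- gNW(k + 1L, j - 1L)
      if (abs(V[i + 1L, k] + wr - target) < .FOLD_EPS &&
          NV[i + 1L, k] + nr == ntarget) {
        tb_V(i + 1L, k)
        if (k + 1L <= j - 1L) tb_W(k + 1L, j - 1L)
        return(invisible())
      }
    }
    stop("internal error: traceback failed in V")
  }
  tb_W <- function(i, j) {
    if (i >= j) return(invisible())
    target <- W[i, j]; ntarget <- NW[i, j]
    if (abs(W[i + 1L, j] - target) < .FOLD_EPS && NW[i + 1L, j] == ntarget)
      return(tb_W(i + 1L, j))
    for (k in (i + min_loop + 1L):j) {
      if (!is.finite(V[i, k])) next
      wr <- gW(k + 1L, j); nr <- gNW(k + 1L, j)
      if (abs(V[i, k] + wr - target) < .FOLD_EPS &&
          NV[i, k] + nr == ntarget) {
        tb_V(i, k)
        if (k + 1L <= j) tb_W(k + 1L, j)
        return(invisible())
      }
    }
    stop("internal error: traceback failed in W")
  }
  if (W[1L, n] < -.FOLD_EPS || NW[1L, n] > 0L) tb_W(1L, n)

  db <- rep(".", n)
  db[pairs > seq_len(n)] <- "("
  db[pairs != 0L & pairs < seq_len(n)] <- ")"
  out <- list(structure = paste(db, collapse = ""),
              mfe = min(W[1L, n], 0), pairs = pairs)
  class(out) <- "fold_result"
  out
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$structure, "\n", sprintf("MFE = %.2f kcal/mol", x$mfe), "\n",
      sep = "")
  invisible(x)
}

# Energy of an explicit pair set under the stacking model (used to
# re-validate structures; sums stacks over adjacent pairs).
structure_energy <- function(codes, pairs) {
  e <- 0
  for (i in seq_along(pairs)) {
    j <- pairs[i]
    if (j <= i) next
    if (i + 1L <= length(pairs) && pairs[i + 1L] == j - 1L && j - 1L > i + 1L)
      e <- e + .STACK_ENERGY[.PAIR_INDEX[codes[i], codes[j]],
                             .PAIR_INDEX[codes[i + 1L], codes[j - 1L]]]
  }
  e
}
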