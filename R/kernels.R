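## Vectorized scoring kernels.
##
## Ranking evaluates every one of the p*(p-1)/2 gene pairs, and the
## transductive classifier re-scores gene subsets once per sample and label
## assignment, so pair scores must come from matrix operations rather than
## per-pair table construction.  The kernels below compute, for all pairs at
## once, the same counts and the same score arithmetic (identical term
## grouping, hence identical floating-point results for the RS backend) as
## the scalar contingency-table path in contingency.R / scores.R.
##
## Count exactness: all cell counts are sums of products of values in
## {0, 0.25, 0.5, 1}, which are exact dyadic rationals, so counts are
## bit-identical no matter the accumulation order.

## kernel variant of .xlog2 with scalar or same-shape denominator
.xk <- function(num, den) {
  out <- num
  p <- num > 0
  dd <- if (length(den) == 1L) den else den[p]
  out[p] <- num[p] * log2(num[p] / dd)
  out
}

## z * log2(z) for proportions (entropy backend)
.zk <- function(z) {
  out <- z
  p <- z > 0
  out[p] <- z[p] * log2(z[p])
  out
}

## endpoints of every gene: midpoint of the two class mean profiles
.kernel_endpoints <- function(X, pos) {
  (colSums(X[!pos, , drop = FALSE]) / sum(!pos) +
   colSums(X[pos, , drop = FALSE]) / sum(pos)) / 2
}

## ">" mass of every cell: 1 above threshold, 0 below, 0.5 on a tie
.kernel_above <- function(X, ep) {
  epm <- matrix(ep, nrow(X), ncol(X), byrow = TRUE)
  (X > epm) + 0.5 * (X == epm)
}

## 2x2 score from count vectors/matrices (a = f+1, b = f+2, c = f-1,
## d = f-2; fp, fm scalars); mirrors complexity()/max_complexity() exactly
.score22 <- function(a, b, c, d, fp, fm, backend, correction) {
  n <- fp + fm
  f1 <- a + c
  f2 <- b + d
  if (backend == "rs") {
    c_row <- -((.xk(a, fp) + .xk(b, fp)) + (.xk(c, fm) + .xk(d, fm)))
    c_col <- -((.xk(a, f1) + .xk(c, f1)) + (.xk(b, f2) + .xk(d, f2)))
    cmax <- n * log2(2) + (-(.xk(fp, n) + .xk(fm, n)))
    s <- (cmax - (c_row + c_col)) / cmax
    if (cmax <= 0) s[] <- 0
    s
  } else if (backend == "entropy") {
    h_row <- -(.zk(a / fp) + .zk(b / fp)) + -(.zk(c / fm) + .zk(d / fm))
    h_col <- (f1 > 0) * -(.zk(a / pmax(f1, 1)) + .zk(c / pmax(f1, 1))) +
             (f2 > 0) * -(.zk(b / pmax(f2, 1)) + .zk(d / pmax(f2, 1)))
    h_max <- 2 * log2(2) + 2 * (-(.zk(fp / n) + .zk(fm / n)))
    (h_max - (h_row + h_col)) / h_max
  } else {  # chi2, with the configured continuity-correction variant
    det <- a * d - b * c
    term <- switch(correction,
                   yates_nofloor = abs(det) - n / 2,
                   yates = pmax(abs(det) - n / 2, 0),
                   none = abs(det))
    stat <- n * term^2 / pmax(fp * fm * f1 * f2, 1e-300)
    stat[f1 == 0 | f2 == 0] <- 0
    stat
  }
}

## 2x4 score from the eight count matrices (vp = list f+1..f+4, vm = f-1..f-4)
.score24 <- function(vp, vm, fp, fm, backend, correction) {
  n <- fp + fm
  fd <- lapply(1:4, function(d) vp[[d]] + vm[[d]])
  if (backend == "rs") {
    rp <- .xk(vp[[1L]], fp) + .xk(vp[[2L]], fp) +
          .xk(vp[[3L]], fp) + .xk(vp[[4L]], fp)
    rm <- .xk(vm[[1L]], fm) + .xk(vm[[2L]], fm) +
          .xk(vm[[3L]], fm) + .xk(vm[[4L]], fm)
    c_row <- -(rp + rm)
    c_col <- -(((.xk(vp[[1L]], fd[[1L]]) + .xk(vm[[1L]], fd[[1L]])) +
                (.xk(vp[[2L]], fd[[2L]]) + .xk(vm[[2L]], fd[[2L]])) +
                (.xk(vp[[3L]], fd[[3L]]) + .xk(vm[[3L]], fd[[3L]]))) +
               (.xk(vp[[4L]], fd[[4L]]) + .xk(vm[[4L]], fd[[4L]])))
    cmax <- n * log2(4) + (-(.xk(fp, n) + .xk(fm, n)))
    list(C = c_row + c_col, C_max = cmax)
  } else if (backend == "entropy") {
    h_row <- -(.zk(vp[[1L]] / fp) + .zk(vp[[2L]] / fp) +
               .zk(vp[[3L]] / fp) + .zk(vp[[4L]] / fp)) +
             -(.zk(vm[[1L]] / fm) + .zk(vm[[2L]] / fm) +
               .zk(vm[[3L]] / fm) + .zk(vm[[4L]] / fm))
    h_col <- 0
    for (d in 1:4) {
      fdd <- pmax(fd[[d]], 1e-300)
      h_col <- h_col +
        (fd[[d]] > 0) * -(.zk(vp[[d]] / fdd) + .zk(vm[[d]] / fdd))
    }
    h_max <- 2 * log2(4) + 4 * (-(.zk(fp / n) + .zk(fm / n)))
    list(C = h_row + h_col, C_max = h_max)
  } else {  # chi2: plain Pearson over cells with positive expectation
    stat <- 0
    for (d in 1:4) {
      ep <- fp * fd[[d]] / n
      em <- fm * fd[[d]] / n
      pos_e <- fd[[d]] > 0
      ep <- pmax(ep, 1e-300); em <- pmax(em, 1e-300)
      stat <- stat + pos_e * ((vp[[d]] - ep)^2 / ep + (vm[[d]] - em)^2 / em)
    }
    list(C = stat, C_max = NULL)
  }
}

## scores of every individual gene under its vertical 2x2 table
.kernel_individual <- function(X, pos, backend = "rs",
                               correction = "yates_nofloor") {
  ep <- .kernel_endpoints(X, pos)
  A <- .kernel_above(X, ep)
  npos <- sum(pos); nneg <- sum(!pos)
  fp1 <- colSums(A[pos, , drop = FALSE])
  fm1 <- colSums(A[!pos, , drop = FALSE])
  .score22(fp1, npos - fp1, fm1, nneg - fm1, npos, nneg, backend, correction)
}

## symmetric p x p matrix of pair scores (horizontal 2x2 + vertical 2x4
## combined per the pair score definition), diagonal fixed at 0
.kernel_pair <- function(X, pos, backend = "rs",
                         correction = "yates_nofloor") {
  p <- ncol(X)
  npos <- sum(pos); nneg <- sum(!pos)
  n <- npos + nneg
  ep <- .kernel_endpoints(X, pos)
  A <- .kernel_above(X, ep)
  Ap <- A[pos, , drop = FALSE];  Bp <- 1 - Ap
  Am <- A[!pos, , drop = FALSE]; Bm <- 1 - Am

  ## vertical 2x4 counts for all pairs: cross-products of the ">" masses
  vp <- list(crossprod(Ap),      crossprod(Ap, Bp),
             crossprod(Bp, Ap),  crossprod(Bp))
  vm <- list(crossprod(Am),      crossprod(Am, Bm),
             crossprod(Bm, Am),  crossprod(Bm))

  ## horizontal 2x2 counts: within-sample order relations, tie mass 0.5
  Hp <- matrix(0, p, p)
  for (i in which(pos)) {
    xi <- X[i, ]
    Hp <- Hp + outer(xi, xi, ">") + 0.5 * outer(xi, xi, "==")
  }
  Hm <- matrix(0, p, p)
  for (i in which(!pos)) {
    xi <- X[i, ]
    Hm <- Hm + outer(xi, xi, ">") + 0.5 * outer(xi, xi, "==")
  }

  if (backend == "rs") {
    ch_row <- -((.xk(Hp, npos) + .xk(npos - Hp, npos)) +
                (.xk(Hm, nneg) + .xk(nneg - Hm, nneg)))
    f1 <- Hp + Hm
    f2 <- (npos - Hp) + (nneg - Hm)
    ch_col <- -((.xk(Hp, f1) + .xk(Hm, f1)) +
                (.xk(npos - Hp, f2) + .xk(nneg - Hm, f2)))
    c_hor <- ch_row + ch_col
    c_hor_max <- n * log2(2) + (-(.xk(npos, n) + .xk(nneg, n)))
    ver <- .score24(vp, vm, npos, nneg, "rs", correction)
    denom <- c_hor_max + ver$C_max
    S <- (denom - (c_hor + ver$C)) / denom
  } else if (backend == "entropy") {
    h_hor <- .score22_entropy_raw(Hp, npos - Hp, Hm, nneg - Hm, npos, nneg)
    ver <- .score24(vp, vm, npos, nneg, "entropy", correction)
    denom <- h_hor$h_max + ver$C_max
    S <- (denom - (h_hor$h + ver$C)) / denom
  } else {
    s_hor <- .score22(Hp, npos - Hp, Hm, nneg - Hm, npos, nneg,
                      "chi2", correction)
    ver <- .score24(vp, vm, npos, nneg, "chi2", correction)
    S <- s_hor + ver$C
  }
  diag(S) <- 0
  dimnames(S) <- list(colnames(X), colnames(X))
  S
}

## raw row+column entropies of a 2x2 table (for the pair combination the
## entropy backend needs observed and maximum separately)
.score22_entropy_raw <- function(a, b, c, d, fp, fm) {
  n <- fp + fm
  f1 <- a + c
  f2 <- b + d
  h_row <- -(.zk(a / fp) + .zk(b / fp)) + -(.zk(c / fm) + .zk(d / fm))
  h_col <- (f1 > 0) * -(.zk(a / pmax(f1, 1e-300)) + .zk(c / pmax(f1, 1e-300))) +
           (f2 > 0) * -(.zk(b / pmax(f2, 1e-300)) + .zk(d / pmax(f2, 1e-300)))
  h_max <- 2 * log2(2) + 2 * (-(.zk(fp / n) + .zk(fm / n)))
  list(h = h_row + h_col, h_max = h_max)
}

## integrated score of every gene: individual score plus its weighted share
## of every pair score; weight_j = s_j / (s_j + s_q), 0/0 taken as 0
.kernel_integrated <- function(X, pos, backend = "rs",
                               correction = "yates_nofloor") {
  s_ind <- .kernel_individual(X, pos, backend, correction)
  S <- .kernel_pair(X, pos, backend, correction)
  p <- length(s_ind)
  denom <- outer(s_ind, s_ind, "+")
  W <- matrix(s_ind, p, p) / denom    # [j, q] = s_j / (s_j + s_q)
  W[!is.finite(W)] <- 0
  contrib <- W * S
  contrib[!is.finite(contrib)] <- 0
  ## accumulate left-to-right from the individual score, one partner at a
  ## time in double precision, matching the literal per-gene loop bit for
  ## bit (rowSums would carry extended-precision intermediates)
  irs <- s_ind
  for (q in seq_len(p)) irs <- irs + contrib[, q]
  list(individual = s_ind, pair = S, integrated = irs)
}
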