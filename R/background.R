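#' Impute missing marker genotypes for regression
#'
#' Missing codes are replaced (for the cofactor regression only) by the
#' conditional expectation `lambda * x_left + rho * x_right` computed from
#' the nearest non-missing flanking markers on the same chromosome; a lone
#' informative side contributes `x * (1 - 2 r)`; individuals with no
#' informative marker on the chromosome get 0 (the unconditional mean).
#'
#' @param genotypes n x m matrix of +1/-1/NA codes, columns in map order.
#' @param map the [genetic_map()] matching the columns.
#' @param population population kind.
#' @return n x m numeric matrix without missing values.
#' @export
impute_genotypes <- function(genotypes, map, population = "DH") {
  stopifnot(inherits(map, "genetic_map"), ncol(genotypes) == nrow(map))
  population <- match_population(population)
  out <- genotypes
  chr_idx <- split(seq_len(nrow(map)), map$chromosome)
  for (cols in chr_idx) {
    pos <- map$position_cM[cols]
    g <- genotypes[, cols, drop = FALSE]
    miss <- which(is.na(g), arr.ind = TRUE)
    if (!nrow(miss)) next
    for (mm in seq_len(nrow(miss))) {
      i <- miss[mm, 1L]; j <- miss[mm, 2L]
      obs <- which(!is.na(g[i, ]))
      left <- obs[obs < j]; right <- obs[obs > j]
      li <- if (length(left)) max(left) else NA_integer_
      ri <- if (length(right)) min(right) else NA_integer_
      val <- if (!is.na(li) && !is.na(ri)) {
        ip <- interval_probabilities(pos[j] - pos[li], pos[ri] - pos[j],
                                     population)
        ip$lambda * g[i, li] + ip$rho * g[i, ri]
      } else if (!is.na(li)) {
        g[i, li] * (1 - 2 * pop_recomb(pos[j] - pos[li], population))
      } else if (!is.na(ri)) {
        g[i, ri] * (1 - 2 * pop_recomb(pos[ri] - pos[j], population))
      } else 0
      out[i, cols[j]] <- val
    }
  }
  out
}

# Forward-entry / backward-removal stepwise regression of one phenotype on
# marker columns, by partial F-tests.  Returns indices and jointly refitted
# coefficients.  Deterministic: p-value ties broken by lower column index.
stepwise_one <- function(X, y, p_in, p_out) {
  keep <- !is.na(y)
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  n <- length(y)
  m <- ncol(X)
  sel <- integer(0)
  candidates <- which(apply(X, 2L, stats::var) > 0)

  partial_p <- function(sel) {
    # drop-one partial F p-value for each selected column
    Xs <- cbind(1, X[, sel, drop = FALSE])
    fit <- stats::lm.fit(Xs, y)
    p <- fit$rank
    df2 <- n - p
    if (df2 < 1) return(rep(0, length(sel)))
    rss <- sum(fit$residuals^2)
    xtxi <- chol2inv(chol(crossprod(Xs)))
    se2 <- diag(xtxi) * rss / df2
    tval2 <- fit$coefficients^2 / se2
    stats::pf(tval2[-1L], 1, df2, lower.tail = FALSE)
  }

  repeat {
    # forward step: best candidate by partial F given current selection
    Xs <- cbind(1, X[, sel, drop = FALSE])
    qrS <- qr(Xs)
    ry <- stats::resid(stats::lm.fit(Xs, y))
    rss0 <- sum(ry^2)
    df2 <- n - qrS$rank - 1L
    if (df2 < 2L) break
    cand <- setdiff(candidates, sel)
    if (!length(cand)) break
    Xc <- X[, cand, drop = FALSE]
    Rc <- Xc - qr.fitted(qrS, Xc)
    ss <- colSums(Rc^2)
    ok <- ss > 1e-10
    if (!any(ok)) break
    add_ss <- (crossprod(Rc[, ok, drop = FALSE], ry)[, 1L])^2 / ss[ok]
    add_ss <- pmin(add_ss, rss0)
    Fval <- add_ss / ((rss0 - add_ss) / df2)
    pval <- stats::pf(Fval, 1, df2, lower.tail = FALSE)
    best <- which.min(pval)          # ties -> lowest index (stable)
    if (pval[best] > p_in) break
    sel <- sort(c(sel, cand[ok][best]))

    # backward sweep: remove while the worst selected exceeds p_out
    repeat {
      pp <- partial_p(sel)
      worst <- which.max(pp)
      if (length(sel) && pp[worst] > p_out) sel <- sel[-worst] else break
    }
  }

  fit <- stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), y)
  list(markers = sel,
       intercept = unname(fit$coefficients[1L]),
       coefficients = unname(fit$coefficients[-1L]))
}

#' Per-environment stepwise cofactor selection
#'
#' Classic forward-entry / backward-removal stepwise regression of each
#' environment's phenotype on all marker columns of the inclusive linear
#' model, with partial F-tests at entry probability `p_in` and removal
#' probability `p_out`.  Selection runs independently per environment;
#' individuals with a missing phenotype are dropped from that environment's
#' regression only; missing marker codes are imputed by
#' [impute_genotypes()] beforehand.
#'
#' @param genotypes n x m marker matrix (+1/-1/NA) in map order, or a
#'   `sim_genotypes` object.
#' @param phenotypes n x e phenotype matrix (NA cells allowed).
#' @param map the [genetic_map()] (needed to impute missing codes; may be
#'   omitted when `genotypes` is a `sim_genotypes`).
#' @param p_in entry probability threshold (default 0.001).
#' @param p_out removal probability threshold (default 0.002);
#'   must satisfy `p_in < p_out`.
#' @param population population kind for imputation.
#' @return object of class `cofactor_model`: list with per-environment
#'   components `markers` (selected column indices), `coefficients`,
#'   `intercept`, plus the imputed genotype matrix in `$X`.
#' @export
stepwise_select <- function(genotypes, phenotypes, map = NULL,
                            p_in = 0.001, p_out = 0.002,
                            population = "DH") {
  if (inherits(genotypes, "sim_genotypes")) {
    if (is.null(map)) map <- genotypes$map
    population <- genotypes$population
    genotypes <- genotypes$markers
  }
  if (p_in >= p_out)
    stop("entry threshold p_in must be stricter (smaller) than p_out")
  phenotypes <- as.matrix(phenotypes)
  if (nrow(phenotypes) != nrow(genotypes))
    stop("genotypes and phenotypes disagree on the number of individuals")
  X <- if (anyNA(genotypes)) {
    if (is.null(map)) stop("map needed to impute missing genotypes")
    impute_genotypes(genotypes, map, population)
  } else genotypes
  env <- lapply(seq_len(ncol(phenotypes)), function(h)
    stepwise_one(X, phenotypes[, h], p_in, p_out))
  structure(list(environments = env, X = X,
                 p_in = p_in, p_out = p_out),
            class = "cofactor_model")
}

#' @export
print.cofactor_model <- function(x, ...) {
  ns <- vapply(x$environments, function(m) length(m$markers), integer(1))
  cat("Cofactor model:", paste(ns, collapse = "/"),
      "markers selected per environment (p_in =", x$p_in,
      ", p_out =", x$p_out, ")\n")
  invisible(x)
}

#' Background-adjusted phenotypes for one marker interval
#'
#' Subtracts from each phenotype the fitted contributions of every selected
#' cofactor except the two markers flanking the current interval.  The
#' intercept is not subtracted.  The adjusted values are constant for all
#' testing positions within the interval.
#'
#' @param phenotypes n x e phenotype matrix.
#' @param model a `cofactor_model` from [stepwise_select()].
#' @param flank integer vector of the two flanking-marker column indices
#'   (use `integer(0)` to subtract all cofactors).
#' @return n x e matrix of adjusted phenotypes.
#' @export
adjust_phenotypes <- function(phenotypes, model, flank = integer(0)) {
  stopifnot(inherits(model, "cofactor_model"))
  phenotypes <- as.matrix(phenotypes)
  out <- phenotypes
  for (h in seq_len(ncol(phenotypes))) {
    mh <- model$environments[[h]]
    use <- !(mh$markers %in% flank)
    if (any(use)) {
      out[, h] <- phenotypes[, h] -
        model$X[, mh$markers[use], drop = FALSE] %*% mh$coefficients[use]
    }
  }
  out
}
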