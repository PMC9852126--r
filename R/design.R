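# Model terms and the design of an additive model.
#
# A design is an ordered list of terms: one implicit intercept, optional
# section constants (treatment-coded, zero for the reference section) and
# smooth terms. Each smooth carries its basis, the covariate column(s) it
# reads, a smoothing policy per penalty ("auto" REML or a fixed value) and
# an optional `by` restriction to one section.

#' Smooth model term
#'
#' @param label term label used in outputs.
#' @param vars name(s) of the covariate column(s) in the data (two for a
#'   tensor smooth).
#' @param basis an `hg_basis`.
#' @param lambda smoothing policy: `"auto"` (REML) or a fixed non-negative
#'   value; recycled over the basis' penalties.
#' @param by optional `list(var =, level =)`: the term applies only where
#'   `data[[var]] == level` (per-section smooths).
#' @return a term description for [hg_design()].
#' @export
smooth_term <- function(label, vars, basis, lambda = "auto", by = NULL) {
  stopifnot(inherits(basis, "hg_basis"))
  lambda <- rep(as.list(lambda), length.out = length(basis$penalties))
  structure(list(type = "smooth", label = label, vars = vars, basis = basis,
                 lambda = lambda, by = by), class = "hg_term")
}

#' Section-constant model term
#'
#' Treatment-coded constants for a labelled factor (e.g. pre/post fluid
#' sections): the reference level's constant is exactly zero and the other
#' levels get one unpenalized coefficient each.
#'
#' @param var name of the factor/character column in the data.
#' @param ref reference level (defaults to the first level seen).
#' @export
factor_term <- function(var, ref = NULL) {
  structure(list(type = "factor", label = var, var = var, ref = ref),
            class = "hg_term")
}

#' Assemble an additive-model design
#'
#' @param ... `hg_term` objects from [smooth_term()] / [factor_term()]. A
#'   single global intercept is always included first.
#' @return an object of class `hg_design`.
#' @export
hg_design <- function(...) {
  terms <- list(...)
  if (length(terms) == 1L && is.list(terms[[1]]) && !inherits(terms[[1]], "hg_term"))
    terms <- terms[[1]]
  stopifnot(all(vapply(terms, inherits, TRUE, "hg_term")))
  labs <- vapply(terms, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("duplicate term labels: ", labs[duplicated(labs)][1])
  structure(list(terms = terms), class = "hg_design")
}

# Realize the design on data: model matrix, per-term column spans, penalty
# descriptors and the unpenalized null-space directions (for the
# identifiability check).
hg_model_matrix <- function(design, data, check_identifiable = TRUE) {
  n <- nrow(data)
  cols <- list(); Xs <- list(); pens <- list(); labels <- character()
  nullmats <- list(); meta <- list()
  p0 <- 0L
  add <- function(label, X) {
    Xs[[length(Xs) + 1L]] <<- X
    cols[[label]] <<- p0 + seq_len(ncol(X))
    labels <<- c(labels, label)
    p0 <<- p0 + ncol(X)
  }
  add("(Intercept)", matrix(1, n, 1))
  nullmats[["(Intercept)"]] <- matrix(1, n, 1)
  for (tm in design$terms) {
    if (tm$type == "factor") {
      f <- data[[tm$var]]
      if (is.null(f)) stop("missing covariate column: ", tm$var)
      f <- as.factor(f)
      lev <- levels(f)
      if (!is.null(tm$ref)) lev <- c(tm$ref, setdiff(lev, tm$ref))
      if (length(lev) < 2L) stop("factor term needs at least 2 levels: ", tm$var)
      Xf <- vapply(lev[-1], function(l) as.numeric(f == l), numeric(n))
      Xf <- matrix(Xf, nrow = n,
                   dimnames = list(NULL, paste0(tm$var, lev[-1])))
      meta[[tm$label]] <- list(levels = lev)
      add(tm$label, Xf)
      nullmats[[tm$label]] <- Xf
    } else {
      xs <- data[tm$vars]
      if (any(vapply(xs, is.null, TRUE))) {
        stop("missing covariate column: ",
             paste(tm$vars[vapply(xs, is.null, TRUE)], collapse = ", "))
      }
      xv <- if (length(tm$vars) == 2L) as.matrix(xs) else xs[[1]]
      Xt <- basis_matrix(tm$basis, xv)
      if (!is.null(tm$by)) {
        ind <- as.numeric(data[[tm$by$var]] == tm$by$level)
        Xt <- Xt * ind
      }
      add(tm$label, Xt)
      # unpenalized directions of this smooth (null space of its total penalty)
      St <- Reduce(`+`, tm$basis$penalties)
      ev <- eigen(St, symmetric = TRUE)
      nulldim <- sum(ev$values < max(ev$values) * 1e-9)
      if (nulldim > 0) {
        Zn <- ev$vectors[, ncol(St) - seq_len(nulldim) + 1L, drop = FALSE]
        nullmats[[tm$label]] <- Xt %*% Zn
      }
      for (j in seq_along(tm$basis$penalties)) {
        pens[[length(pens) + 1L]] <- list(
          term = tm$label, idx = cols[[tm$label]],
          S = tm$basis$penalties[[j]], policy = tm$lambda[[j]],
          name = if (length(tm$basis$penalties) > 1L)
            paste0(tm$label, ".", j) else tm$label)
      }
    }
  }
  X <- do.call(cbind, Xs)
  # identifiability of the unpenalized part: the null-space columns of all
  # terms together must be full rank, otherwise no penalty can separate them
  N <- do.call(cbind, nullmats)
  if (check_identifiable && qr(N)$rank < ncol(N)) {
    stop("unidentifiable model: unpenalized parts of terms {",
         paste(names(nullmats), collapse = ", "),
         "} are confounded; center the smooths or drop a term")
  }
  list(X = X, cols = cols, pens = pens, labels = labels, meta = meta)
}
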