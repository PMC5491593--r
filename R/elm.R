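#' Extreme-learning-machine hyperparameters
#'
#' The classifier maps a d-dimensional input through a fixed random matrix
#' `W_in ~ U[-1, 1]` into D hidden units, standardizes each hidden
#' pre-activation (statistics estimated on the training pass and frozen),
#' applies `F(z) = sin^2(eta * z + phi)`, and trains only a least-squares
#' readout on the hidden states. An ensemble of `n_ensemble` independent
#' `W_in` realizations votes by simple majority.
#'
#' @param D hidden-layer size (reference analysis: 350).
#' @param eta input scaling (reference: 0.1).
#' @param phi activation phase (reference: 2.1); `sin^2` has period `pi` in
#'   `phi`, so `phi` and `phi + pi` are equivalent.
#' @param n_ensemble number of ensemble members (reference: 100).
#' @param seed master seed from which member seeds are derived.
#' @param ridge optional L2 penalty on the readout (default 0: plain OLS
#'   with a minimum-norm pseudoinverse when rank-deficient).
#' @return An object of class `elm_params`.
#' @export
elm_params <- function(D = 350, eta = 0.1, phi = 2.1, n_ensemble = 100,
                       seed = 1L, ridge = 0) {
  stopifnot(D >= 1, n_ensemble >= 1, eta > 0, ridge >= 0)
  structure(
    list(
      D = as.integer(D), eta = eta, phi = phi,
      n_ensemble = as.integer(n_ensemble), seed = as.integer(seed),
      ridge = ridge
    ),
    class = "elm_params"
  )
}

#' Initialize one untrained ensemble member
#'
#' Draws `W_in` (d x D) uniformly from `[-1, 1]`, reproducibly from
#' `member_seed`. Standardization statistics and readout weights are unset
#' until [fit_readout()].
#'
#' @param d input dimension.
#' @param params an [elm_params()].
#' @param member_seed integer seed for this member's `W_in`.
#' @return An object of class `elm_model`.
#' @export
init_member <- function(d, params, member_seed) {
  stopifnot(d >= 1)
  set.seed(member_seed)
  w <- matrix(stats::runif(d * params$D, -1, 1), nrow = d, ncol = params$D)
  structure(
    list(
      W_in = w, params = params, d = as.integer(d),
      center = NULL, scale = NULL, W_out = NULL,
      member_seed = as.integer(member_seed)
    ),
    class = "elm_model"
  )
}

#' Hidden-layer states
#'
#' `z = standardize(X %*% W_in)` per hidden unit, then
#' `r = sin^2(eta * z + phi)`, so every state lies in `[0, 1]`. With
#' `fit_standardization = TRUE` the per-unit mean and standard deviation are
#' estimated from `X` and stored on the model (training pass); otherwise the
#' stored statistics are reused, so no test-set information leaks into the
#' representation.
#'
#' @param model an `elm_model`.
#' @param X numeric matrix, examples x d.
#' @param fit_standardization estimate and store standardization statistics.
#' @return List with `R` (examples x D hidden states) and `model` (updated
#'   when fitting).
#' @export
hidden_states <- function(model, X, fit_standardization = FALSE) {
  stopifnot(is.matrix(X))
  if (ncol(X) != model$d) {
    stop("input dimension mismatch: got ", ncol(X), ", expected ", model$d,
      call. = FALSE
    )
  }
  Z <- X %*% model$W_in
  if (fit_standardization) {
    mu <- colMeans(Z)
    sdv <- sqrt(colSums(sweep(Z, 2, mu)^2) / (nrow(Z) - 1))
    if (any(sdv <= .Machine$double.eps * 100)) {
      stop("degenerate hidden unit(s): zero variance pre-activation", call. = FALSE)
    }
    model$center <- mu
    model$scale <- sdv
  } else if (is.null(model$center)) {
    stop("standardization statistics unset: fit the model first", call. = FALSE)
  }
  Zs <- sweep(sweep(Z, 2, model$center), 2, model$scale, "/")
  R <- sin(model$params$eta * Zs + model$params$phi)^2
  list(R = R, model = model)
}

#' Train the linear readout
#'
#' Ordinary least squares of the targets on the hidden states plus an
#' intercept, via the SVD-based minimum-norm pseudoinverse (rank-deficient
#' designs get the minimum-norm solution). With `ridge > 0` a standard
#' Tikhonov term on the non-intercept weights is used instead.
#'
#' @param model an `elm_model` with standardization fitted.
#' @param R examples x D hidden states from the training pass.
#' @param y numeric target vector (binary coding +1 / -1).
#' @return The model with `W_out` (length D + 1, intercept first) set.
#' @export
fit_readout <- function(model, R, y) {
  stopifnot(is.matrix(R), nrow(R) == length(y), nrow(R) > 1)
  if (!all(is.finite(R))) stop("non-finite hidden states", call. = FALSE)
  A <- cbind(1, R)
  ridge <- model$params$ridge
  if (ridge > 0) {
    p <- ncol(A)
    pen <- diag(ridge, p)
    pen[1, 1] <- 0 # do not penalize the intercept
    model$W_out <- solve(crossprod(A) + pen, crossprod(A, y))[, 1]
  } else {
    sv <- svd(A)
    tol <- max(dim(A)) * .Machine$double.eps * sv$d[1]
    pos <- sv$d > tol
    model$W_out <- as.vector(
      sv$v[, pos, drop = FALSE] %*%
        ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    )
  }
  model
}

#' Fit one ensemble member end to end
#'
#' @param model an initialized `elm_model`.
#' @param X training inputs (examples x d).
#' @param y training targets (+1 / -1).
#' @return Trained model.
#' @export
fit_member <- function(model, X, y) {
  hs <- hidden_states(model, X, fit_standardization = TRUE)
  fit_readout(hs$model, hs$R, y)
}

#' Predict with one trained member
#'
#' Continuous output `o = W_out %*% [1; r]` and its sign as the class label;
#' an output of exactly 0 maps to the positive class.
#'
#' @param model trained `elm_model`.
#' @param X inputs (examples x d).
#' @return List with `output` (continuous) and `label` (+1 / -1).
#' @export
predict_member <- function(model, X) {
  if (is.null(model$W_out)) stop("model has no trained readout", call. = FALSE)
  hs <- hidden_states(model, X, fit_standardization = FALSE)
  o <- as.vector(cbind(1, hs$R) %*% model$W_out)
  list(output = o, label = ifelse(o >= 0, 1L, -1L))
}

# Derive one sub-seed per member from the master seed, staying below 2^31.
member_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Fit a majority-vote ensemble
#'
#' Each member gets an independent `W_in` realization (seed derived from the
#' master seed by a counter scheme) and is fitted on the same training data.
#'
#' @param X training inputs (examples x d).
#' @param y training targets (+1 / -1).
#' @param params an [elm_params()].
#' @return An object of class `elm_ensemble`.
#' @export
fit_ensemble <- function(X, y, params) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  seeds <- member_seeds(params$seed, params$n_ensemble)
  members <- lapply(seq_len(params$n_ensemble), function(i) {
    fit_member(init_member(ncol(X), params, seeds[i]), X, y)
  })
  structure(list(members = members, params = params), class = "elm_ensemble")
}

#' Majority-vote prediction
#'
#' Each member votes +1 or -1 per example; the ensemble label is the
#' majority, with an exact tie resolved to the positive (pathological)
#' class. The positive-vote fraction is returned as a score for ROC
#' analysis.
#'
#' @param ens an `elm_ensemble`.
#' @param X inputs (examples x d).
#' @return List with `label` (+1 / -1) and `vote_fraction` (share of members
#'   voting +1).
#' @export
predict_ensemble <- function(ens, X) {
  votes <- vapply(
    ens$members, function(m) predict_member(m, X)$label,
    integer(nrow(X))
  )
  if (nrow(X) == 1) votes <- matrix(votes, nrow = 1)
  vf <- rowMeans(votes == 1L)
  list(label = ifelse(vf >= 0.5, 1L, -1L), vote_fraction = vf)
}
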