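#' Encode a surgery as a feature vector
#'
#' Input representation of the surrogate network: the 36 Zernike elevation
#' coefficients of the pre-operative cornea on an 8 mm aperture, followed by
#' two fixed-size segment slots. Each slot carries: family one-hot (SI5,
#' SI6), arc-length one-hot over the family's four catalog arcs, thickness
#' scaled by 350 um, the bisecting line encoded as (sin a, cos a), a
#' presence flag, and a tensor-product block: for each of the eight
#' catalog types, the thickness-scaled axis harmonics
#' `type * (th/350) * (1, sin k a, cos k a; k = 1..7)`. An absent second
#' segment leaves its slot all-zero with presence 0.
#'
#' The tensor block reflects the geometry of the problem: the elevation
#' change induced by an arc segment scales with thickness and rotates
#' rigidly with its bisecting line, so each Zernike coefficient of the
#' change is, for a given catalog type, a thickness-scaled single
#' harmonic in the axis angle (of order equal to the coefficient's
#' azimuthal frequency, at most 7). In this basis the induced change is a
#' linear function of the encoding, which makes the implant effect
#' identifiable from cohorts of realistic size instead of asking the
#' network to synthesize high axis harmonics from a single (sin, cos)
#' pair.
#'
#' @param preop [zernike_coef] at 8 mm, radial order 7 (36 values).
#' @param segments list of 1 or 2 [segment_spec] objects.
#' @return named numeric feature vector of length 296 (36 + 2 x 130).
#' @export
encode_features <- function(preop, segments) {
  stopifnot(inherits(preop, "zernike_coef"))
  if (length(preop) != 36L || abs(attr(preop, "pupil_diameter_mm") - 8) > 1e-9) {
    stop("preop coefficients must be order 7 (36 terms) on an 8 mm aperture",
         call. = FALSE)
  }
  if (inherits(segments, "segment_spec")) segments <- list(segments)
  if (length(segments) > 2L) {
    stop("at most 2 segments can be encoded", call. = FALSE)
  }
  if (length(segments) < 1L) stop("at least 1 segment required", call. = FALSE)
  kmax <- 7L
  cat8 <- keraring_catalog()
  type_names <- sprintf("%s_%d", cat8$model, cat8$arc_deg)
  harm_names <- c("h0", paste0(rep(c("sin", "cos"), kmax),
                               rep(seq_len(kmax), each = 2)))
  slot_names <- c("si5", "si6", paste0("arc", 1:4), "thickness",
                  "axis_sin", "axis_cos", "present",
                  paste0(rep(type_names, each = length(harm_names)), "_",
                         rep(harm_names, length(type_names))))
  slot <- function(s) {
    out <- numeric(10L + 8L * (1L + 2L * kmax))
    if (!is.null(s)) {
      fam <- as.numeric(c(s$model == "SI5", s$model == "SI6"))
      arcs <- cat8$arc_deg[cat8$model == s$model]
      arc1h <- as.numeric(arcs == s$arc_deg)
      a <- 2 * pi * (s$bisecting_line_deg %% 360) / 360
      k <- seq_len(kmax)
      th <- s$thickness_um / 350
      harm <- c(1, as.vector(rbind(sin(k * a), cos(k * a))))
      type1h <- as.numeric(cat8$model == s$model & cat8$arc_deg == s$arc_deg)
      out <- c(fam, arc1h, th, sin(a), cos(a), 1,
               as.vector(outer(harm, type1h)) * th)
    }
    names(out) <- slot_names
    out
  }
  s1 <- slot(segments[[1]])
  s2 <- slot(if (length(segments) == 2L) segments[[2]] else NULL)
  out <- c(as.numeric(preop), s1, s2)
  names(out) <- c(names(preop),
                  paste0("seg1_", names(s1)), paste0("seg2_", names(s2)))
  out
}

# ---- feedforward network internals (one hidden tanh layer stack) ----

nn_init <- function(layer_sizes, seed) {
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(layer_sizes) - 1L)) {
      fan_in <- layer_sizes[l]
      W[[l]] <- matrix(stats::runif(fan_in * layer_sizes[l + 1L], -1, 1) /
                         sqrt(fan_in),
                       fan_in, layer_sizes[l + 1L])
      b[[l]] <- numeric(layer_sizes[l + 1L])
    }
    # linear input->output bypass; zero here, optionally warm-started by
    # the trainer at the regularized least-squares solution
    skip <- matrix(0, layer_sizes[1], layer_sizes[length(layer_sizes)])
    list(W = W, b = b, skip = skip)
  })
}

# forward pass; returns activations per layer (tanh hidden, linear output
# plus the linear bypass)
nn_forward <- function(par, X) {
  L <- length(par$W)
  acts <- vector("list", L + 1L)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(acts[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
    acts[[l + 1L]] <- if (l < L) tanh(Z) else Z
  }
  acts[[L + 1L]] <- acts[[L + 1L]] + X %*% par$skip
  acts
}

# mean squared error over all outputs and analytic gradients
nn_loss_grad <- function(par, X, Y) {
  n <- nrow(X)
  acts <- nn_forward(par, X)
  L <- length(par$W)
  Yhat <- acts[[L + 1L]]
  err <- Yhat - Y
  loss <- mean(err^2)
  delta <- 2 * err / (n * ncol(Y))
  gskip <- crossprod(X, delta)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(par$W[[l]])) * (1 - acts[[l]]^2)
    }
  }
  list(loss = loss, gW = gW, gb = gb, gskip = gskip)
}

standardize_fit <- function(M) {
  mu <- colMeans(M)
  sd <- apply(M, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}
standardize_apply <- function(M, st) {
  sweep(sweep(M, 2, st$mu, "-"), 2, st$sd, "/")
}

#' Fit the post-operative-elevation surrogate network
#'
#' Trains a feedforward neural network by full-batch backpropagation with
#' momentum to map (pre-operative Zernike elevation vector + implant
#' encoding) to the post-operative Zernike elevation vector on the same
#' 8 mm aperture. Only surgically successful cases (see [success_filter()])
#' are accepted as training material. Features and targets are standardized
#' per column from the training data; the normalization is stored in the
#' fitted model. The momentum update is
#' `dW_t = -lr * grad + momentum * dW_{t-1}`.
#'
#' The network's internal regression target is the surgically induced
#' change (post-operative minus pre-operative coefficients), standardized
#' per coefficient; the predicted change is added back to the
#' pre-operative vector, so [predict.icrs_surrogate()] always returns the
#' full post-operative decomposition. The architecture is a tanh
#' hidden-layer stack with linear output plus a zero-initialized linear
#' input-to-output bypass for any residual linear dependence on the inputs.
#'
#' @param cases list of [case_record] objects, all passing the success
#'   filter; at least 10.
#' @param hidden integer vector of hidden-layer sizes (default 40).
#' @param learning_rate gradient-descent step (default 0.01).
#' @param momentum momentum coefficient (default 0.9).
#' @param epochs full-batch epochs (default 2000).
#' @param weight_decay L2 penalty coefficient on the hidden-path weights
#'   (not biases, not the linear bypass); default 1e-3. Shrinks spurious
#'   nonlinear pathways so the implant effect is attributed to the implant
#'   features rather than interpolated from the pre-operative coefficients.
#' @param init_bypass warm-start the linear bypass at the ridge
#'   least-squares solution of the standardized regression (default TRUE).
#'   Gradient descent converges very slowly along the ill-conditioned
#'   directions of the correlated implant-basis features; solving the
#'   linear part in closed form and letting backpropagation refine the
#'   whole network removes that bottleneck. Deterministic.
#' @param seed RNG seed for the weight initialization.
#' @param check_success set `FALSE` only for controlled experiments with
#'   synthetic teachers; clinical training must keep the filter on.
#' @return object of class `icrs_surrogate`: layer sizes, weights and
#'   biases, input/output normalization, the training-loss trajectory, and
#'   the training metadata.
#' @export
icrs_surrogate <- function(cases, hidden = 40, learning_rate = 0.01,
                           momentum = 0.9, epochs = 2000,
                           weight_decay = 1e-3, init_bypass = TRUE,
                           seed = 1, check_success = TRUE) {
  stopifnot(is.list(cases))
  if (length(cases) < 10L) {
    stop("need at least 10 training cases, got ", length(cases), call. = FALSE)
  }
  if (check_success) {
    ok <- vapply(cases, function(cs) success_filter(cs)$is_success, TRUE)
    if (!all(ok)) {
      stop(sum(!ok), " case(s) do not pass the success filter; only ",
           "successful cases may train the surrogate", call. = FALSE)
    }
  }
  X <- t(vapply(cases, function(cs) encode_features(cs$preop_zernike,
                                                    cs$implant),
                numeric(296)))
  Y <- t(vapply(cases, function(cs) as.numeric(cs$postop_zernike),
                numeric(36)))
  # the learning target is the surgically induced change: the post-operative
  # vector is dominated by the pre-operative one, and differencing focuses
  # the squared-error objective on the implant effect itself
  Y <- Y - X[, 1:36, drop = FALSE]
  in_norm <- standardize_fit(X)
  out_norm <- standardize_fit(Y)
  Xs <- standardize_apply(X, in_norm)
  Ys <- standardize_apply(Y, out_norm)
  layer_sizes <- c(ncol(Xs), hidden, ncol(Ys))
  par <- nn_init(layer_sizes, seed)
  if (init_bypass) {
    G <- crossprod(Xs) / nrow(Xs)
    ridge <- 1e-6 * mean(diag(G))
    par$skip <- solve(G + diag(ridge, ncol(Xs)), crossprod(Xs, Ys) / nrow(Xs))
  }
  vW <- lapply(par$W, function(w) w * 0)
  vb <- lapply(par$b, function(b) b * 0)
  vskip <- par$skip * 0
  trajectory <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    g <- nn_loss_grad(par, Xs, Ys)
    if (!is.finite(g$loss)) {
      stop("training diverged (non-finite loss) at epoch ", ep,
           "; lower the learning rate (currently ", learning_rate, ")",
           call. = FALSE)
    }
    for (l in seq_along(par$W)) {
      vW[[l]] <- -learning_rate * (g$gW[[l]] + weight_decay * par$W[[l]]) +
        momentum * vW[[l]]
      vb[[l]] <- -learning_rate * g$gb[[l]] + momentum * vb[[l]]
      par$W[[l]] <- par$W[[l]] + vW[[l]]
      par$b[[l]] <- par$b[[l]] + vb[[l]]
    }
    vskip <- -learning_rate * g$gskip + momentum * vskip
    par$skip <- par$skip + vskip
    trajectory[ep] <- g$loss
  }
  final <- nn_loss_grad(par, Xs, Ys)$loss
  structure(list(layer_sizes = layer_sizes, W = par$W, b = par$b,
                 skip = par$skip,
                 in_norm = in_norm, out_norm = out_norm,
                 feature_names = colnames(X),
                 loss_trajectory = trajectory,
                 training = list(n_cases = length(cases),
                                 learning_rate = learning_rate,
                                 momentum = momentum, epochs = epochs,
                                 weight_decay = weight_decay,
                                 seed = seed, final_mse = final)),
            class = "icrs_surrogate")
}

# forward pass on raw (unstandardized) feature rows -> postop coefficient
# rows: the network emits the predicted change, added back to the
# pre-operative coefficients
surrogate_forward <- function(model, Xraw) {
  if (ncol(Xraw) != model$layer_sizes[1]) {
    stop("feature count ", ncol(Xraw), " does not match the model input size ",
         model$layer_sizes[1], call. = FALSE)
  }
  Xs <- standardize_apply(Xraw, model$in_norm)
  acts <- nn_forward(list(W = model$W, b = model$b, skip = model$skip), Xs)
  Ys <- acts[[length(acts)]]
  delta <- sweep(sweep(Ys, 2, model$out_norm$sd, "*"), 2, model$out_norm$mu, "+")
  Xraw[, 1:36, drop = FALSE] + delta
}

#' Predict the post-operative elevation coefficients
#'
#' @param object a fitted [icrs_surrogate].
#' @param preop pre-operative [zernike_coef] (8 mm, order 7).
#' @param segments list of 1-2 [segment_spec].
#' @param ... unused.
#' @return predicted post-operative [zernike_coef] at 8 mm in micrometres.
#' @export
predict.icrs_surrogate <- function(object, preop, segments, ...) {
  x <- encode_features(preop, segments)
  y <- surrogate_forward(object, matrix(x, nrow = 1L))
  zernike_coef(as.numeric(y), max_order = 7, pupil_diameter_mm = 8)
}

#' @export
print.icrs_surrogate <- function(x, ...) {
  cat("ICRS outcome surrogate (feedforward network, backpropagation with momentum)\n")
  cat("  architecture :", paste(x$layer_sizes, collapse = " - "),
      "(tanh hidden, linear output)\n")
  cat(sprintf("  training     : %d successful cases, lr %g, momentum %g, %d epochs, seed %d\n",
              x$training$n_cases, x$training$learning_rate,
              x$training$momentum, x$training$epochs, x$training$seed))
  cat(sprintf("  final MSE    : %.3g (standardized units)\n", x$training$final_mse))
  invisible(x)
}

#' @export
summary.icrs_surrogate <- function(object, ...) {
  tr <- object$loss_trajectory
  out <- list(layer_sizes = object$layer_sizes,
              n_weights = sum(vapply(object$W, length, 0L)) +
                sum(vapply(object$b, length, 0L)) + length(object$skip),
              training = object$training,
              loss_first = tr[1], loss_final = tr[length(tr)],
              loss_reduction = tr[1] / tr[length(tr)])
  class(out) <- "summary.icrs_surrogate"
  out
}

#' @export
print.summary.icrs_surrogate <- function(x, ...) {
  cat("Surrogate network summary\n")
  cat("  layers       :", paste(x$layer_sizes, collapse = " - "), "\n")
  cat("  parameters   :", x$n_weights, "\n")
  cat(sprintf("  MSE epoch 1  : %.4g\n  MSE final    : %.4g  (x%.1f reduction)\n",
              x$loss_first, x$loss_final, x$loss_reduction))
  invisible(x)
}

#' @export
coef.icrs_surrogate <- function(object, ...) {
  list(W = object$W, b = object$b, skip = object$skip)
}

#' @export
plot.icrs_surrogate <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trajectory), x$loss_trajectory, type = "l",
                 log = "y", xlab = "epoch", ylab = "training MSE (standardized)",
                 main = "Surrogate training loss", ...)
  invisible(x)
}

#' Residuals of the surrogate on a case set
#'
#' @param object a fitted [icrs_surrogate].
#' @param cases list of [case_record]; defaults require explicit cases since
#'   the training set is not stored.
#' @param ... unused.
#' @return matrix of per-case, per-coefficient residuals (predicted minus
#'   observed post-operative coefficients, um).
#' @export
residuals.icrs_surrogate <- function(object, cases, ...) {
  X <- t(vapply(cases, function(cs) encode_features(cs$preop_zernike,
                                                    cs$implant),
                numeric(296)))
  Y <- t(vapply(cases, function(cs) as.numeric(cs$postop_zernike),
                numeric(36)))
  surrogate_forward(object, X) - Y
}

#' Save a surrogate model as JSON
#'
#' Versioned plain-text container with layer sizes, weights, normalization
#' and training metadata at full double precision; byte-stable for a given
#' model.
#'
#' @param model a fitted [icrs_surrogate].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_surrogate <- function(model, path) {
  stopifnot(inherits(model, "icrs_surrogate"))
  payload <- list(format = "icrsplan-surrogate", version = 1L,
                  target = "postop_minus_preop",
                  layer_sizes = model$layer_sizes,
                  W = lapply(model$W, function(w) as.numeric(w)),
                  b = model$b,
                  skip = as.numeric(model$skip),
                  in_norm = model$in_norm, out_norm = model$out_norm,
                  feature_names = model$feature_names,
                  loss_trajectory = model$loss_trajectory,
                  training = model$training)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' Load a surrogate model from JSON
#'
#' @param path file written by [write_surrogate()].
#' @return an [icrs_surrogate].
#' @export
read_surrogate <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "icrsplan-surrogate")) {
    stop("not an icrsplan surrogate model file: ", path, call. = FALSE)
  }
  ls <- as.integer(p$layer_sizes)
  W <- lapply(seq_len(length(ls) - 1L), function(l) {
    matrix(p$W[[l]], ls[l], ls[l + 1L])
  })
  structure(list(layer_sizes = ls, W = W, b = lapply(p$b, as.numeric),
                 skip = matrix(p$skip, ls[1], ls[length(ls)]),
                 in_norm = lapply(p$in_norm, as.numeric),
                 out_norm = lapply(p$out_norm, as.numeric),
                 feature_names = p$feature_names,
                 loss_trajectory = as.numeric(p$loss_trajectory),
                 training = p$training),
            class = "icrs_surrogate")
}
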