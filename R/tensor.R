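# Mode-product tensor algebra: Tucker-style reconstruction of volume frames
# from three factor matrices and a constant core tensor, frame splitting and
# merging for 4D series, and a gradient-based factor fitter.

#' Mode-n product of a tensor with a matrix
#'
#' Multiplies an n-way array along its `mode`-th axis: the output extent
#' along that mode equals `nrow(m)`, all other extents are unchanged.  An
#' identity matrix leaves the tensor unchanged, and products along distinct
#' modes commute.
#'
#' @param x an n-way numeric array.
#' @param m a matrix whose column count equals `dim(x)[mode]`.
#' @param mode axis index (1-based).
#' @return An array of dimension `dim(x)` with entry `mode` replaced by
#'   `nrow(m)`.
#' @examples
#' g <- array(1, c(2, 2, 2))
#' mode_product(g, diag(2) * 2, 1)[1, 1, 1]   # 2
#' @export
mode_product <- function(x, m, mode) {
  d <- dim(x)
  if (is.null(d)) stop("`x` must be an array", call. = FALSE)
  mode <- as.integer(mode)
  if (mode < 1L || mode > length(d)) {
    stop(sprintf("mode %d is outside 1..%d", mode, length(d)), call. = FALSE)
  }
  m <- as.matrix(m)
  if (ncol(m) != d[mode]) {
    stop(sprintf("matrix has %d columns but the tensor extent along mode %d is %d",
                 ncol(m), mode, d[mode]), call. = FALSE)
  }
  perm <- c(mode, seq_along(d)[-mode])
  xp <- aperm(x, perm)
  dim(xp) <- c(d[mode], prod(d[-mode]))
  yp <- m %*% xp
  dim(yp) <- c(nrow(m), d[-mode])
  aperm(yp, order(perm))
}

#' Construct a constant core (kernel) tensor
#'
#' The small 3-way array that couples the factor matrices in the Tucker-style
#' reconstruction `X = G x1 A x2 S x3 C`.  The default is a superdiagonal
#' (identity-like) core; `type = "random"` draws seeded standard-normal
#' entries.  The core is held fixed ("constant") during factor fitting.
#'
#' @param ranks integer vector of three mode ranks, all >= 1.
#' @param type `"superdiag"` (default) or `"random"`.
#' @param seed integer seed (used by `type = "random"`).
#' @return A numeric 3-way array with a `"core_type"` attribute.
#' @export
core_tensor <- function(ranks, type = c("superdiag", "random"), seed = 1L) {
  type <- match.arg(type)
  ranks <- as.integer(ranks)
  if (length(ranks) != 3L || any(ranks < 1L)) {
    stop("`ranks` must be three integers >= 1", call. = FALSE)
  }
  g <- array(0, ranks)
  if (type == "superdiag") {
    for (r in seq_len(min(ranks))) g[r, r, r] <- 1
  } else {
    g <- with_seed(seed, array(rnorm(prod(ranks)), ranks))
  }
  attr(g, "core_type") <- type
  g
}

#' Reconstruct a 3D volume frame from factors and a core
#'
#' Computes `G x1 A x2 S x3 C`, the composite of the three mode factor
#' matrices and the core tensor.  Deterministic; shape compatibility is
#' checked mode by mode.
#'
#' @param core a 3-way array with ranks `(r1, r2, r3)`.
#' @param factors a list of three matrices with shapes `(d1 x r1)`,
#'   `(d2 x r2)`, `(d3 x r3)` (modes may be annotated coronal / sagittal /
#'   axial by the caller; the algebra is mode-order only).
#' @return A `(d1, d2, d3)` array.
#' @export
reconstruct_frame <- function(core, factors) {
  if (length(dim(core)) != 3L) stop("`core` must be a 3-way array", call. = FALSE)
  if (!is.list(factors) || length(factors) != 3L) {
    stop("`factors` must be a list of three matrices", call. = FALSE)
  }
  x <- core
  for (mode in 1:3) x <- mode_product(x, factors[[mode]], mode)
  x
}

#' Split a 4D tensor into 3D frames / merge frames back
#'
#' `split_frames()` unpacks a `(d1, d2, d3, T)` array into `T` volumes in
#' temporal order; `merge_frames()` is its exact inverse and is also how a
#' 4D reference tensor is assembled from per-frame reconstructions.
#'
#' @param tensor4d a 4-way array.
#' @param frames a list of 3D arrays sharing one shape.
#' @return A list of 3D arrays, or a 4-way array.
#' @export
split_frames <- function(tensor4d) {
  d <- dim(tensor4d)
  if (length(d) != 4L) stop("`tensor4d` must be a 4-way array", call. = FALSE)
  lapply(seq_len(d[4]), function(t) array(tensor4d[, , , t], d[1:3]))
}

#' @rdname split_frames
#' @export
merge_frames <- function(frames) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop("`frames` must be a nonempty list of 3D arrays", call. = FALSE)
  }
  d <- dim(frames[[1]])
  if (length(d) != 3L) stop("frames must be 3-way arrays", call. = FALSE)
  ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(ok)) stop("all frames must share one shape", call. = FALSE)
  array(unlist(frames, use.names = FALSE), c(d, length(frames)))
}

.factor_nonlin <- list(
  identity = list(fn = function(x) x, grad = function(x) 1),
  relu = list(fn = function(x) pmax(x, 0), grad = function(x) as.numeric(x > 0)),
  sigmoid = list(fn = function(x) 1 / (1 + exp(-x)),
                 grad = function(x) { s <- 1 / (1 + exp(-x)); s * (1 - s) })
)

# Unfolding of G x_{modes != m} factors, along mode m: the matrix M with
# Xhat_(m) = f(F_m) %*% M.
.partial_unfolding <- function(core, mapped, m) {
  x <- core
  for (mode in setdiff(1:3, m)) x <- mode_product(x, mapped[[mode]], mode)
  d <- dim(x)
  perm <- c(m, setdiff(1:3, m))
  xp <- aperm(x, perm)
  dim(xp) <- c(d[m], prod(d[-m]))
  xp
}

#' Fit factor matrices to a volume frame
#'
#' Desk-scale factor fitter: given a fixed ("constant") core tensor, finds
#' three factor matrices minimizing the squared reconstruction error
#' `|X - G x1 f(A) x2 f(S) x3 f(C)|^2`.  With the identity map (the
#' default) each factor is updated in turn by its exact least-squares
#' solution given the others (block alternating minimization), which is
#' monotone and converges far faster than a fixed-step gradient on this
#' multilinear problem; for the non-linear maps (`"relu"`, `"sigmoid"`) the
#' fitter falls back to gradient descent with backtracking step halving
#' (the step is halved until the loss decreases and regrown mildly after
#' successful steps).  Either way the recorded loss history is
#' non-increasing.  Initialization is seeded `N(0, 0.1)`.  This fitter
#' recovers the reconstruction, not the factors themselves (factor
#' identifiability is not claimed).
#'
#' @param frame a 3-way array.
#' @param core a 3-way array with ranks at most the frame extents.
#' @param nonlin elementwise factor map: `"identity"`, `"relu"` or
#'   `"sigmoid"`.
#' @param seed integer seed for initialization.
#' @param n_starts number of seeded starts for the identity-map fit (the
#'   fixed-core matching problem has local minima; starts after the first
#'   run only when the previous ones did not reach `start_tol`).
#' @param start_tol relative reconstruction error below which a start is
#'   accepted without trying further ones (default 1e-8).
#' @param max_iter iteration cap (default 2000).
#' @param lr initial step size (default 0.05).
#' @param tol stop when the relative loss improvement over an iteration
#'   falls below `tol` (default 1e-12).
#' @return A list: `factors` (the mapped factor matrices `f(A)`, `f(S)`,
#'   `f(C)`), `raw` (unmapped parameters), `loss_history`, and
#'   `relative_error` (final Frobenius error over the frame norm).
#' @export
fit_factors <- function(frame, core, nonlin = c("identity", "relu", "sigmoid"),
                        seed = 1L, n_starts = 4L, start_tol = 1e-8,
                        max_iter = 2000L, lr = 0.05, tol = 1e-12) {
  nonlin <- match.arg(nonlin)
  d <- dim(frame)
  r <- dim(core)
  if (length(d) != 3L || length(r) != 3L) {
    stop("`frame` and `core` must be 3-way arrays", call. = FALSE)
  }
  if (any(r > d)) stop("core ranks must not exceed the frame extents", call. = FALSE)
  nl <- .factor_nonlin[[nonlin]]

  raw <- with_seed(seed, lapply(1:3, function(m) {
    matrix(rnorm(d[m] * r[m], sd = 0.1), d[m], r[m])
  }))
  frame_norm2 <- sum(frame^2)

  eval_loss <- function(raw) {
    mapped <- lapply(raw, nl$fn)
    xhat <- reconstruct_frame(core, mapped)
    list(loss = sum((xhat - frame)^2), mapped = mapped, xhat = xhat)
  }

  cur <- eval_loss(raw)
  history <- cur$loss

  if (nonlin == "identity") {
    # Exact block least-squares sweeps over the three factors (each update
    # minimizes the loss in that factor given the others, so the loss is
    # monotone).  Matching a *fixed* core is prone to swamps from random
    # starts, so the fit also tries a subspace start: a truncated
    # higher-order SVD gives mode subspaces U_m and a free core H with
    # X ~ H x1 U1 x2 U2 x3 U3; the residual problem H ~ G x1 Q1 x2 Q2 x3 Q3
    # is tiny (r_m x r_m blocks) and is solved by the same sweeps under
    # several cheap seeded restarts, after which A_m = U_m Q_m is polished
    # on the full problem.  The better of the two starts is returned.
    sweeps <- function(x, g, mapped, n_sweeps, hist0) {
      dd <- dim(x)
      hist <- hist0
      for (it in seq_len(n_sweeps)) {
        for (m in 1:3) {
          M <- .partial_unfolding(g, mapped, m)
          perm <- c(m, setdiff(1:3, m))
          Xp <- aperm(x, perm)
          dim(Xp) <- c(dd[m], prod(dd[-m]))
          Gm <- M %*% t(M)
          mapped[[m]] <- t(solve(Gm + 1e-12 * diag(nrow(Gm)), M %*% t(Xp)))
        }
        l <- sum((reconstruct_frame(g, mapped) - x)^2)
        improvement <- (hist[length(hist)] - l) /
          max(hist[length(hist)], .Machine$double.xmin)
        hist <- c(hist, min(l, hist[length(hist)]))
        if (improvement < tol) break
      }
      list(mapped = mapped, history = hist)
    }

    one_start <- function(seed_k) {
    raw <- with_seed(seed_k, lapply(1:3, function(m) {
      matrix(rnorm(d[m] * r[m], sd = 0.1), d[m], r[m])
    }))
    direct <- sweeps(frame, core, raw, max_iter, eval_loss(raw)$loss)

    hosvd <- with_seed(seed_k + 1L, {
      U <- lapply(1:3, function(m) {
        perm <- c(m, setdiff(1:3, m))
        Xp <- aperm(frame, perm)
        dim(Xp) <- c(d[m], prod(d[-m]))
        svd(Xp, nu = r[m], nv = 0)$u
      })
      H <- frame
      for (m in 1:3) H <- mode_product(H, t(U[[m]]), m)
      best_q <- NULL
      h_norm2 <- sum(H^2)
      for (rs in 1:15) {
        Q0 <- lapply(r, function(rm) matrix(rnorm(rm * rm), rm, rm))
        fitq <- sweeps(H, core, Q0, 150, sum((reconstruct_frame(core, Q0) - H)^2))
        if (is.null(best_q) || min(fitq$history) < min(best_q$history)) best_q <- fitq
        if (min(best_q$history) < 1e-10 * h_norm2) break
      }
      A0 <- Map(function(u, q) u %*% q, U, best_q$mapped)
      sweeps(frame, core, A0, 150,
             sum((reconstruct_frame(core, A0) - frame)^2))
    })

    chosen <- if (min(hosvd$history) < min(direct$history)) hosvd else direct

    # quasi-Newton polish: escapes the slow linear tail of the sweeps
    sizes <- vapply(1:3, function(m) d[m] * r[m], numeric(1))
    unflatten <- function(p) {
      off <- cumsum(c(0, sizes))
      lapply(1:3, function(m) matrix(p[(off[m] + 1):off[m + 1]], d[m], r[m]))
    }
    obj <- function(p) sum((reconstruct_frame(core, unflatten(p)) - frame)^2)
    grd <- function(p) {
      fs <- unflatten(p)
      e <- reconstruct_frame(core, fs) - frame
      unlist(lapply(1:3, function(m) {
        M <- .partial_unfolding(core, fs, m)
        perm <- c(m, setdiff(1:3, m))
        ep <- aperm(e, perm)
        dim(ep) <- c(d[m], prod(d[-m]))
        2 * ep %*% t(M)
      }))
    }
    pol <- stats::optim(unlist(chosen$mapped), obj, grd, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (pol$value < min(chosen$history)) {
      chosen$mapped <- unflatten(pol$par)
      chosen$history <- c(chosen$history, pol$value)
    }
    chosen
    }

    best <- NULL
    for (k in seq_len(max(1L, as.integer(n_starts)))) {
      cand <- one_start(seed + 2L * (k - 1L))
      if (is.null(best) || min(cand$history) < min(best$history)) best <- cand
      rel_k <- sqrt(min(best$history) / max(frame_norm2, .Machine$double.xmin))
      if (rel_k < start_tol) break
    }
    final_loss <- min(best$history)
    return(list(factors = best$mapped, raw = best$mapped,
                loss_history = best$history,
                relative_error = sqrt(final_loss / max(frame_norm2, .Machine$double.xmin)),
                nonlin = nonlin, seed = seed))
  }

  step <- lr
  for (it in seq_len(max_iter)) {
    e <- cur$xhat - frame
    grads <- vector("list", 3L)
    for (m in 1:3) {
      M <- .partial_unfolding(core, cur$mapped, m)
      perm <- c(m, setdiff(1:3, m))
      ep <- aperm(e, perm)
      dim(ep) <- c(d[m], prod(d[-m]))
      g_mapped <- 2 * ep %*% t(M)
      grads[[m]] <- g_mapped * nl$grad(raw[[m]])
    }
    gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (gnorm == 0) break
    accepted <- FALSE
    for (halving in 0:40) {
      cand <- Map(function(p, g) p - step * g, raw, grads)
      cand_eval <- eval_loss(cand)
      if (is.finite(cand_eval$loss) && cand_eval$loss <= cur$loss) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    improvement <- (cur$loss - cand_eval$loss) / max(cur$loss, .Machine$double.xmin)
    raw <- cand
    cur <- cand_eval
    history <- c(history, cur$loss)
    step <- step * 1.25
    if (improvement < tol) break
  }
  list(factors = cur$mapped, raw = raw, loss_history = history,
       relative_error = sqrt(cur$loss / max(frame_norm2, .Machine$double.xmin)),
       nonlin = nonlin, seed = seed)
}
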