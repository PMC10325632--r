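# Training driver for the equation learner: an Adam gradient loop (compiled)
# minimizing squared error plus lambda * L1/2*.  The penalty is held at zero
# for a warm-up fraction of the epochs so units are not pruned before the
# fit term has shaped them.

#' Training configuration for the equation learner
#'
#' @param epochs number of full passes over the training data.
#' @param lr Adam learning rate.
#' @param lambda sparsity-penalty weight applied after warm-up (>= 0).
#' @param warmup_frac fraction of epochs trained with `lambda = 0`
#'   (default 0.25).
#' @param seed integer seed (required); controls minibatch shuffling and is
#'   recorded so a run can be replayed exactly.
#' @param train_frac fraction of records a caller should assign to training
#'   when splitting (default 0.8; recorded for provenance, the split itself
#'   is done by [split_triplets()]).
#' @param batch_size minibatch size; `NULL` (default) trains full-batch,
#'   which is deterministic.
#' @param standardize center and scale the target to unit standard
#'   deviation during optimization, folding the affine map back into the
#'   linear read-out afterwards (default `TRUE`).  This equalizes gradient
#'   scales across targets of very different ranges without changing what
#'   the network represents; the recorded loss history is in standardized
#'   units.
#' @param final_lr_factor,final_lr_frac after `final_lr_frac` of the epochs
#'   the learning rate is multiplied once by `final_lr_factor` (a polishing
#'   phase; defaults 0.1 and 0.8).
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(epochs = 1500L, lr = 0.02, lambda = 1e-3,
                         warmup_frac = 0.25, seed, train_frac = 0.8,
                         batch_size = NULL, standardize = TRUE,
                         final_lr_factor = 0.1, final_lr_frac = 0.8) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (!(train_frac > 0 && train_frac < 1)) {
    stop("`train_frac` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  structure(list(epochs = as.integer(epochs), lr = lr, lambda = lambda,
                 warmup_frac = warmup_frac, seed = as.integer(seed),
                 train_frac = train_frac,
                 batch_size = if (is.null(batch_size)) 0L else as.integer(batch_size),
                 standardize = isTRUE(standardize),
                 final_lr_factor = final_lr_factor,
                 final_lr_frac = final_lr_frac),
            class = "train_config")
}

#' Train an equation-learner network
#'
#' Gradient-based minimization (Adam) of the squared-error loss plus
#' `lambda` times the smoothed-L1/2 penalty over all weights and biases.
#' The penalty weight is zero for the first `warmup_frac` of the epochs.
#' Training is reproducible given the network (whose initialization is
#' seeded) and the config seed.  If the loss becomes non-finite the run
#' aborts with an error reporting the epoch.
#'
#' @param network an [build_network()] result.
#' @param dataset the training portion of a `triplet_dataset` (the caller is
#'   responsible for the train/test split; see [split_triplets()]).
#' @param config a [train_config()].
#' @return The trained `eql_network`, with an attached numeric
#'   `$loss_history` (one entry per epoch) and the config under `$config`.
#' @examples
#' m <- outer(seq(-1, 1, length = 20), seq(-1, 1, length = 20),
#'            function(a, b) 0.5 * a)
#' ds <- matrix_to_triplets(m)
#' net <- build_network(operator_set(unary = "id", binary = NULL),
#'                      depth = 1, units = c(id = 2), seed = 1)
#' fit <- train_eql(net, ds, train_config(epochs = 200, lambda = 0, seed = 1))
#' tail(fit$loss_history, 1)
#' @export
train_eql <- function(network, dataset, config) {
  stopifnot(inherits(network, "eql_network"),
            inherits(dataset, "triplet_dataset"),
            inherits(config, "train_config"))
  X <- .triplet_features(dataset,
                         use_derivative = network$operators$use_derivative)
  y <- dataset$records$y
  y_mu <- 0; y_sd <- 1
  if (config$standardize) {
    if (!is.null(network$y_scale)) {
      # warm start: keep the scale the network was trained under
      y_mu <- network$y_scale$mu
      y_sd <- network$y_scale$sd
    } else {
      y_mu <- mean(y)
      y_sd <- sd(y)
      if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
    }
    y <- (y - y_mu) / y_sd
  }

  layers_in <- lapply(network$layers, function(l) {
    list(W = l$W, b = l$b,
         unary_code = unname(.fl_unary_codes[l$unary]),
         binary_code = if (length(l$binary)) unname(.fl_binary_codes[l$binary]) else integer(0))
  })
  warmup <- as.integer(floor(config$warmup_frac * config$epochs))
  out <- eql_train_cpp(X, y, layers_in, network$W_out, network$b_out,
                       config$epochs, config$lr, config$lambda, warmup,
                       network$a, config$batch_size, config$seed,
                       config$final_lr_factor, config$final_lr_frac)
  if (out$diverged_epoch > 0) {
    stop(sprintf("training diverged (non-finite loss) at epoch %d",
                 out$diverged_epoch), call. = FALSE)
  }
  for (l in seq_along(network$layers)) {
    network$layers[[l]]$W <- out$layers[[l]]$W
    network$layers[[l]]$b <- as.vector(out$layers[[l]]$b)
  }
  network$W_out <- matrix(out$W_out, nrow = 1L)
  network$b_out <- as.numeric(out$b_out)
  # target scale kept outside the trained parameterization, so coefficient
  # pruning at theta operates on the scale the penalty saw
  network$y_scale <- list(mu = y_mu, sd = y_sd)
  network$trained <- TRUE
  network$loss_history <- as.vector(out$loss_history)
  network$config <- config
  network
}

#' Fit a factor surface with multiple seeded restarts
#'
#' Convenience driver for distilling a factor matrix into a formula: splits
#' the triplets 80/20, trains several restarts that vary the seed, the
#' oscillatory initialization scale, and the depth, and keeps the restart
#' with the best tolerance-band accuracy on the training portion.  Restart
#' selection never looks at the held-out test portion.
#'
#' @param dataset a `triplet_dataset` for the full matrix.
#' @param seed master seed; restart seeds and the split seed derive from it.
#' @param restarts number of restarts (default 4).
#' @param epochs epochs per restart.
#' @param lambda sparsity weight after warm-up.
#' @param tau tolerance used for the selection accuracy (default 0.05).
#' @param units unit complement per layer (see [build_network()]).
#' @param depths integer vector recycled over restarts (default `c(2, 3)`).
#' @param osc_scales numeric vector recycled over restarts: initialization
#'   scale for sin/cos frequencies (default `c(1, 6, 18, 1)`), letting some
#'   restarts start in a high-frequency regime.
#' @param train_frac fraction of records used for training (default 0.8).
#' @param finetune_segments,finetune_epochs,finetune_candidates optional
#'   successive-halving fine-tune after the restarts: the top
#'   `finetune_candidates` restarts (by training accuracy) each receive one
#'   probe segment of `finetune_epochs` epochs, then the best candidate
#'   receives the remaining segments; the checkpoint with the highest
#'   training accuracy seen anywhere is kept.  Each segment re-anneals the
#'   learning rate, which keeps improving slowly-converging oscillatory
#'   fits; probing more than one candidate matters because runs that lock
#'   onto an oscillatory structure improve in jumps while stuck runs crawl.
#'   Default 0 segments (off).
#' @return A list: `network` (best trained network), `formula` (extracted at
#'   the network's threshold), `train`, `test` (the split), `report`
#'   (held-out [verification_accuracy()] of the best network) and
#'   `selection` (per-restart training accuracies).
#' @export
fit_surface_formula <- function(dataset, seed, restarts = 4L, epochs = 1500L,
                                lambda = 1e-3, tau = 0.05,
                                units = c(id = 2L, square = 1L, exp = 1L,
                                          sin = 3L, cos = 3L, logabs = 1L,
                                          prod = 3L),
                                depths = c(2L, 3L),
                                osc_scales = c(1, 6, 18, 1),
                                train_frac = 0.8,
                                finetune_segments = 0L,
                                finetune_epochs = 2000L,
                                finetune_candidates = 2L) {
  stopifnot(inherits(dataset, "triplet_dataset"))
  split <- split_triplets(dataset, train_frac = train_frac, seed = seed)
  use_dy <- dataset$has_derivative
  candidates <- list()
  sel <- data.frame(restart = integer(0), depth = integer(0),
                    osc_scale = numeric(0), train_accuracy = numeric(0))
  train_acc <- function(net) {
    verification_accuracy(net, split$train, tau = tau)$accuracy
  }
  for (r in seq_len(restarts)) {
    depth <- depths[((r - 1L) %% length(depths)) + 1L]
    osc <- osc_scales[((r - 1L) %% length(osc_scales)) + 1L]
    ops <- operator_set(use_derivative = use_dy)
    net <- build_network(ops, depth = depth, units = units,
                         seed = seed + 1000L * r, osc_scale = osc)
    cfg <- train_config(epochs = epochs, lambda = lambda,
                        seed = seed + 1000L * r)
    net <- train_eql(net, split$train, cfg)
    acc <- train_acc(net)
    sel <- rbind(sel, data.frame(restart = r, depth = depth, osc_scale = osc,
                                 train_accuracy = acc))
    candidates[[r]] <- list(net = net, acc = acc)
  }
  ord <- order(-vapply(candidates, `[[`, numeric(1), "acc"))
  best <- candidates[[ord[1L]]]
  if (finetune_segments > 0L) {
    # probe segment for each surviving candidate, then commit to the best
    probe <- candidates[ord[seq_len(min(finetune_candidates, restarts))]]
    for (p in seq_along(probe)) {
      cfg <- train_config(epochs = finetune_epochs, lambda = lambda,
                          seed = seed + 777L * p)
      probe[[p]]$net <- train_eql(probe[[p]]$net, split$train, cfg)
      probe[[p]]$acc <- train_acc(probe[[p]]$net)
      if (probe[[p]]$acc > best$acc) best <- probe[[p]]
    }
    cur <- probe[[which.max(vapply(probe, `[[`, numeric(1), "acc"))]]$net
    for (s in seq_len(finetune_segments - 1L)) {
      cfg <- train_config(epochs = finetune_epochs, lambda = lambda,
                          seed = seed + 777L * (length(probe) + s))
      cur <- train_eql(cur, split$train, cfg)
      acc <- train_acc(cur)
      if (acc > best$acc) best <- list(net = cur, acc = acc)
    }
  }
  report <- verification_accuracy(best$net, split$test, tau = tau)
  list(network = best$net,
       formula = extract_formula(best$net),
       train = split$train, test = split$test,
       report = report, selection = sel)
}
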