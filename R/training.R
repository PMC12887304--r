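## Reliability-weighted supervised training on window-level cumulative
## free-energy labels. Optimizer: AdamW (decoupled weight decay, biases
## excluded from decay) with linear warm-up, reduce-on-plateau and early
## stopping; model selection by best validation loss. Everything is
## deterministic given the seed.

#' Inverse-variance reliability weight
#'
#' `w = 1 / (sigma^2 + epsilon^2)`: high-precision labels dominate, noisy
#' labels are down-weighted, and `epsilon` bounds the weight of a
#' zero-uncertainty label.
#'
#' @param sigma Label uncertainty in kcal/mol (>= 0).
#' @param epsilon Regularizer in kcal/mol (> 0, default 0.1).
#' @return Unitless raw weight(s); rescale per batch with
#'   [rescale_weights()].
#' @export
reliability_weight <- function(sigma, epsilon = 0.1) {
  stopifnot(all(sigma >= 0), epsilon > 0)
  1 / (sigma^2 + epsilon^2)
}

#' Rescale a batch of weights to mean 1
#'
#' @param w Raw weights (>= 0, not all zero).
#' @return Weights averaging exactly 1.
#' @export
rescale_weights <- function(w) {
  if (all(w == 0)) alch_stop("all-zero weights", "alch_weight_error")
  w / mean(w)
}

#' Weighted mean squared error
#'
#' `sum(w * (pred - target)^2) / sum(w)`, in kcal^2/mol^2.
#'
#' @param predictions,targets Numeric vectors of equal length.
#' @param weights Non-negative weights, not all zero.
#' @return Scalar loss.
#' @export
weighted_mse <- function(predictions, targets, weights) {
  stopifnot(length(predictions) == length(targets),
            length(weights) == length(targets), all(weights >= 0))
  if (all(weights == 0)) alch_stop("all-zero weights", "alch_weight_error")
  sum(weights * (predictions - targets)^2) / sum(weights)
}

#' RMSE and Pearson correlation
#'
#' RMSE is always reported; the Pearson correlation is undefined for
#' zero-variance input, in which case `pearson_r` is `NA` and a warning of
#' class `alch_eval_warning` is raised.
#'
#' @param predictions,targets Numeric vectors (>= 2 points).
#' @return List with `rmse` (kcal/mol) and `pearson_r`.
#' @export
evaluate <- function(predictions, targets) {
  stopifnot(length(predictions) == length(targets))
  if (length(predictions) < 2)
    alch_stop("need at least 2 points for Pearson r", "alch_eval_error")
  r <- if (stats::sd(predictions) == 0 || stats::sd(targets) == 0) {
    warning(warningCondition("Pearson r undefined for zero-variance input",
                             class = "alch_eval_warning"))
    NA_real_
  } else stats::cor(predictions, targets)
  list(rmse = sqrt(mean((predictions - targets)^2)), pearson_r = r)
}

## ---- AdamW ------------------------------------------------------------

.adamw_init <- function(params) {
  list(m = zero_grads(params), v = zero_grads(params), t = 0L)
}

.adamw_step <- function(params, grads, state, lr, weight_decay,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    upd <- (state$m[[k]] / c1) / (sqrt(state$v[[k]] / c2) + eps)
    wd <- if (grepl("\\.b", k)) 0 else weight_decay  # no decay on biases
    params[[k]] <- params[[k]] - lr * (upd + wd * params[[k]])
  }
  list(params = params, state = state)
}

## ---- batched loss + gradient ------------------------------------------

# rows: data.frame with pair_id, leg_id, lambda, target, weight (raw).
# Returns loss and full-parameter gradient. Graph forward passes are shared
# across all windows/legs of one pair.
.batch_loss_grad <- function(rows, pairs, params, with_grad = TRUE) {
  w <- rescale_weights(rows$weight)
  sw <- sum(w)
  grads <- if (with_grad) zero_grads(params) else NULL
  loss <- 0
  for (pid in unique(rows$pair_id)) {
    sub <- rows[rows$pair_id == pid, , drop = FALSE]
    wsub <- w[rows$pair_id == pid]
    pr <- pairs[[pid]]
    fA <- .forward_graph(pr$graph_a, params, keep_cache = with_grad)
    fB <- .forward_graph(pr$graph_b, params, keep_cache = with_grad)
    dgA <- 0; dgB <- 0
    for (leg in unique(sub$leg_id)) {
      sel <- sub$leg_id == leg
      ord <- order(sub$lambda[sel])
      lams <- sub$lambda[sel][ord]
      tg <- sub$target[sel][ord]
      wl <- wsub[sel][ord]
      fh <- .forward_head(fA$g, fB$g, as.integer(leg), lams, params)
      r <- fh$F - tg
      loss <- loss + sum(wl * r^2)
      if (with_grad) {
        dF <- 2 * wl * r / sw
        bh <- .backward_head(fh$cache, dF, params, grads)
        grads <- bh$grads
        dgA <- dgA + bh$dgA
        dgB <- dgB + bh$dgB
      }
    }
    if (with_grad) {
      grads <- .backward_graph(pr$graph_a, params, fA$cache, dgA, grads)
      grads <- .backward_graph(pr$graph_b, params, fB$cache, dgB, grads)
    }
  }
  list(loss = loss / sw, grads = grads)
}

## ---- training loop -----------------------------------------------------

#' Train the model on window-level labels
#'
#' @param data List with `pairs` (named list of `alch_graph_pair`) and
#'   `labels` (data frame with columns `pair_id`, `leg_id`, `lambda`,
#'   `cumulative_dG_kcal_mol`, `sigma_kcal_mol`), e.g. from
#'   [gen_dataset()] or [read_label_table()].
#' @param config Configuration list (see [alch_config()]); the keys used
#'   here are `lr`, `weight_decay`, `warmup_steps`, `plateau_factor`,
#'   `plateau_patience`, `early_stop_patience`, `batch_size`, `n_epochs`,
#'   `val_fraction`, `epsilon_weight`, `use_reliability_weights`, `seed`
#'   and the architecture keys.
#' @param params Optional starting parameters (default: fresh
#'   [init_params()]).
#' @param val_pairs Optional character vector of pair ids to hold out for
#'   validation; default: a seeded random `val_fraction` of pairs.
#' @param verbose Print one line per epoch (default `FALSE`).
#' @return List of class `alch_fit`: `params` (best-validation weights),
#'   `log` (per-epoch data frame), `best_val_loss`, `val_pairs`,
#'   `config`.
#' @export
train_model <- function(data, config = alch_default_config(), params = NULL,
                        val_pairs = NULL, verbose = FALSE) {
  labels <- data$labels
  pairs <- data$pairs
  stopifnot(nrow(labels) >= 1, length(pairs) >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  if (is.null(params)) params <- init_params(config, seed = config$seed)

  rows <- data.frame(pair_id = as.character(labels$pair_id),
                     leg_id = as.integer(labels$leg_id),
                     lambda = as.numeric(labels$lambda),
                     target = as.numeric(labels$cumulative_dG_kcal_mol),
                     sigma = as.numeric(labels$sigma_kcal_mol),
                     stringsAsFactors = FALSE)
  stopifnot(all(is.finite(rows$target)), all(rows$sigma >= 0))
  rows$weight <- if (isTRUE(config$use_reliability_weights))
    reliability_weight(rows$sigma, config$epsilon_weight) else
      rep(1, nrow(rows))

  ids <- names(pairs)
  if (is.null(val_pairs)) {
    n_val <- max(1L, round(config$val_fraction * length(ids)))
    val_pairs <- sample(ids, n_val)
  }
  tr_rows <- rows[!(rows$pair_id %in% val_pairs), , drop = FALSE]
  va_rows <- rows[rows$pair_id %in% val_pairs, , drop = FALSE]
  if (nrow(tr_rows) == 0 || nrow(va_rows) == 0)
    alch_stop("training/validation split is empty", "alch_train_error")

  state <- .adamw_init(params)
  lr_scale <- 1
  best_val <- Inf; best_params <- params
  stall <- 0L; plateau_stall <- 0L
  step <- 0L
  log <- data.frame()

  tr_pair_ids <- unique(tr_rows$pair_id)
  for (epoch in seq_len(config$n_epochs)) {
    ord <- sample(tr_pair_ids)
    ## batches: consecutive pairs until batch_size samples are reached
    batch <- character(0); count <- 0L
    flush <- function(batch) {
      brows <- tr_rows[tr_rows$pair_id %in% batch, , drop = FALSE]
      lg <- .batch_loss_grad(brows, pairs, params)
      if (!is.finite(lg$loss))
        alch_stop(sprintf("non-finite training loss at epoch %d", epoch),
                  "alch_train_error")
      step <<- step + 1L
      warm <- min(1, step / max(1L, config$warmup_steps))
      lr <- config$lr * warm * lr_scale
      res <- .adamw_step(params, lg$grads, state, lr, config$weight_decay)
      params <<- res$params; state <<- res$state
      lg$loss
    }
    ep_losses <- c()
    for (pid in ord) {
      batch <- c(batch, pid)
      count <- count + sum(tr_rows$pair_id == pid)
      if (count >= config$batch_size) {
        ep_losses <- c(ep_losses, flush(batch))
        batch <- character(0); count <- 0L
      }
    }
    if (length(batch) > 0) ep_losses <- c(ep_losses, flush(batch))

    val_loss <- .batch_loss_grad(va_rows, pairs, params, with_grad = FALSE)$loss
    lr_now <- config$lr * min(1, step / max(1L, config$warmup_steps)) * lr_scale
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = mean(ep_losses),
                                 val_loss = val_loss, lr = lr_now))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e",
                      epoch, mean(ep_losses), val_loss, lr_now))
    if (val_loss < best_val - 1e-8) {
      best_val <- val_loss; best_params <- params
      stall <- 0L; plateau_stall <- 0L
    } else {
      stall <- stall + 1L; plateau_stall <- plateau_stall + 1L
      if (plateau_stall >= config$plateau_patience) {
        lr_scale <- lr_scale * config$plateau_factor
        plateau_stall <- 0L
      }
      if (stall >= config$early_stop_patience) break
    }
  }
  structure(list(params = best_params, log = log, best_val_loss = best_val,
                 val_pairs = val_pairs, config = config),
            class = "alch_fit")
}

#' @export
print.alch_fit <- function(x, ...) {
  cat(sprintf("<alch_fit: %d epochs, best validation loss %.4f (%d val pairs)>\n",
              nrow(x$log), x$best_val_loss, length(x$val_pairs)))
  invisible(x)
}

#' Predict every labelled window of a dataset
#'
#' @param data Dataset list (`pairs` + `labels`) as for [train_model()].
#' @param params `alch_params`.
#' @param pair_ids Optional subset of pair ids.
#' @return The label data frame with an added `predicted_dG_kcal_mol`
#'   column.
#' @export
predict_windows <- function(data, params, pair_ids = NULL) {
  labels <- data$labels
  if (!is.null(pair_ids))
    labels <- labels[labels$pair_id %in% pair_ids, , drop = FALSE]
  out <- labels
  out$predicted_dG_kcal_mol <- NA_real_
  for (pid in unique(labels$pair_id)) {
    pr <- data$pairs[[as.character(pid)]]
    for (leg in unique(labels$leg_id[labels$pair_id == pid])) {
      sel <- which(out$pair_id == pid & out$leg_id == leg)
      sel <- sel[order(out$lambda[sel])]
      prof <- predict_profile(pr, as.integer(leg), out$lambda[sel], params)
      out$predicted_dG_kcal_mol[sel] <- prof$cumulative_dG
    }
  }
  out
}

#' Read a window-level label table from CSV
#'
#' Expected columns: `pair_id`, `leg_id`, `lambda`,
#' `cumulative_dG_kcal_mol`, `sigma_kcal_mol`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_label_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "leg_id", "lambda", "cumulative_dG_kcal_mol",
            "sigma_kcal_mol")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    alch_stop(paste("label table missing column(s):",
                    paste(miss, collapse = ", ")), "alch_format_error")
  tab
}
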