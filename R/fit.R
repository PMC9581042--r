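# Model fitting: the interpeprank() estimator and its S3 methods, plus
# ensembles and checkpoint I/O.

#' Fit a decoy-scoring graph network
#'
#' Trains the edge-conditioned graph convolution network on labeled decoy
#' graphs (cross-entropy over normalized-LRMSD bins, ADAM optimizer,
#' default learning rate 0.001, up to 1000 epochs) with training-time edge
#' dropout. When a validation set is supplied, per-epoch validation loss,
#' Spearman correlation of score vs normalized LRMSD, and precision/recall
#' at score 0.5 are logged, and the returned weights are those of the epoch
#' with the best combined criterion (minimum rank-sum of validation loss,
#' negative Spearman and negative F1). Training and validation sets must
#' not share target or homology-group identifiers.
#'
#' @param graphs List of labeled `ipr_graph` objects (labels must carry
#'   `lrmsd`; `target_id`/`group_id` are used for the disjointness check).
#' @param validation Optional list of labeled `ipr_graph` objects.
#' @param config Network architecture, an [ipr_network_config()].
#' @param learning_rate ADAM learning rate.
#' @param max_epochs Maximum number of epochs.
#' @param batch_size Minibatch size in graphs.
#' @param seed RNG seed controlling initialization, shuffling and edge
#'   dropout; fits are fully reproducible given the seed.
#' @param verbose Print a progress line per epoch.
#' @return An object of class `interpeprank` with `predict`, `print`,
#'   `summary`, `coef`, `fitted`, `residuals` and `plot` methods.
#' @export
interpeprank <- function(graphs, validation = NULL,
                         config = ipr_network_config(),
                         learning_rate = 0.001, max_epochs = 1000L,
                         batch_size = 64L, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(config, "ipr_network_config"), max_epochs >= 1,
            learning_rate >= 0, batch_size >= 1)
  cl <- match.call()
  batch <- ipr_batch(graphs)
  if (anyNA(batch$lrmsd)) stopf("all training graphs need an lrmsd label")
  bins <- ipr_assign_bin(ipr_normalize_lrmsd(batch$lrmsd), config$n_bins)
  valb <- NULL
  if (!is.null(validation)) {
    valb <- ipr_batch(validation)
    if (anyNA(valb$lrmsd)) stopf("all validation graphs need an lrmsd label")
    tro <- intersect(stats::na.omit(batch$target_id), stats::na.omit(valb$target_id))
    gro <- intersect(stats::na.omit(batch$group_id), stats::na.omit(valb$group_id))
    if (length(tro) || length(gro))
      stopf("training and validation sets overlap (targets: %s; groups: %s)",
            paste(tro, collapse = ","), paste(gro, collapse = ","))
    val_bins <- ipr_assign_bin(ipr_normalize_lrmsd(valb$lrmsd), config$n_bins)
  }

  fit <- with_seed(seed, {
    params <- init_params(config)
    flat <- flatten_params(params)
    st <- adam_state(length(flat))
    history <- list()
    candidates <- list()
    n <- batch$n_graphs

    for (epoch in seq_len(max_epochs)) {
      perm <- sample(n)
      losses <- numeric(0L)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1L, n)]
        sub <- ipr_subbatch(batch, idx)
        fw <- nn_forward(sub, params, config, dropout = config$edge_dropout,
                         keep_cache = TRUE)
        lg <- ce_loss_grad(fw$probs, bins[idx])
        fw$dlogits <- lg$dlogits
        grads <- nn_backward(sub, params, config, fw)
        upd <- adam_step(flat, flatten_params(grads), st, learning_rate)
        flat <- upd$theta; st <- upd$state
        params <- relist_params(flat, params)
        losses <- c(losses, lg$loss)
      }
      row <- data.frame(epoch = epoch, train_loss = mean(losses),
                        val_loss = NA_real_, val_spearman = NA_real_,
                        val_precision = NA_real_, val_recall = NA_real_,
                        val_f1 = NA_real_)
      if (!is.null(valb)) {
        vf <- nn_forward(valb, params, config, dropout = 0)
        vl <- ce_loss_grad(vf$probs, val_bins)$loss
        vs <- ipr_score_from_probs(vf$probs)
        rho <- if (stats::sd(valb$lrmsd_norm) > 0 && stats::sd(vs) > 0)
          ipr_spearman(vs, valb$lrmsd_norm) else 0
        pred <- vs >= 0.5; pos <- valb$lrmsd_norm > 0.5
        tp <- sum(pred & pos)
        prec <- if (sum(pred) > 0) tp / sum(pred) else 0
        rec <- if (sum(pos) > 0) tp / sum(pos) else 0
        f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
        row$val_loss <- vl; row$val_spearman <- rho
        row$val_precision <- prec; row$val_recall <- rec; row$val_f1 <- f1
        # keep weight snapshots for epochs not dominated on
        # (loss asc, spearman desc, f1 desc); the rank-sum winner is
        # always non-dominated, so it is guaranteed to be retained.
        dominated <- any(vapply(candidates, function(cd)
          cd$loss <= vl && cd$rho >= rho && cd$f1 >= f1 &&
            (cd$loss < vl || cd$rho > rho || cd$f1 > f1), logical(1L)))
        if (!dominated) {
          candidates <- Filter(function(cd)
            !(vl <= cd$loss && rho >= cd$rho && f1 >= cd$f1 &&
                (vl < cd$loss || rho > cd$rho || f1 > cd$f1)), candidates)
          candidates[[length(candidates) + 1L]] <-
            list(epoch = epoch, loss = vl, rho = rho, f1 = f1, flat = flat)
        }
      }
      history[[epoch]] <- row
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  rho %.3f", epoch,
                        row$train_loss, row$val_loss, row$val_spearman))
    }
    history <- do.call(rbind, history)

    if (!is.null(valb)) {
      rk <- rank(history$val_loss) + rank(-history$val_spearman) +
        rank(-history$val_f1)
      best_epoch <- which.min(rk)
      hit <- Filter(function(cd) cd$epoch == best_epoch, candidates)
      if (length(hit)) flat <- hit[[1L]]$flat
      params <- relist_params(flat, params)
    } else {
      best_epoch <- max_epochs
    }
    list(params = params, history = history, best_epoch = best_epoch)
  })

  tf <- nn_forward(batch, fit$params, config, dropout = 0)
  obj <- structure(list(
    weights = fit$params, config = config, history = fit$history,
    best_epoch = fit$best_epoch, learning_rate = learning_rate,
    batch_size = batch_size, seed = seed, n_train = batch$n_graphs,
    n_validation = if (is.null(valb)) 0L else valb$n_graphs,
    fitted_scores = ipr_score_from_probs(tf$probs),
    train_lrmsd_norm = batch$lrmsd_norm, train_ids = batch$id,
    call = cl), class = "interpeprank")
  obj
}

#' @export
print.interpeprank <- function(x, ...) {
  cat("Edge-conditioned graph network decoy scorer\n")
  cat(sprintf("  %d bins, embedding %d, conv [%s], dense [%s], %s pooling\n",
              x$config$n_bins, x$config$embedding_dim,
              paste(x$config$conv_channels, collapse = ", "),
              paste(x$config$dense_sizes, collapse = ", "), x$config$pooling))
  cat(sprintf("  trained on %d decoys (%d validation), %d epochs, selected epoch %d\n",
              x$n_train, x$n_validation, nrow(x$history), x$best_epoch))
  invisible(x)
}

#' @export
summary.interpeprank <- function(object, ...) {
  h <- object$history[object$best_epoch, ]
  structure(list(config = object$config, n_params = n_params(object$weights),
                 n_train = object$n_train, n_validation = object$n_validation,
                 epochs = nrow(object$history), best_epoch = object$best_epoch,
                 best_metrics = h, seed = object$seed), class = "summary.interpeprank")
}

#' @export
print.summary.interpeprank <- function(x, ...) {
  cat(sprintf("Decoy scorer: %d parameters, %d training decoys, seed %d\n",
              x$n_params, x$n_train, x$seed))
  cat(sprintf("Selected epoch %d/%d:\n", x$best_epoch, x$epochs))
  print(x$best_metrics, row.names = FALSE)
  invisible(x)
}

#' @export
coef.interpeprank <- function(object, ...) object$weights

#' @export
fitted.interpeprank <- function(object, ...) {
  stats::setNames(object$fitted_scores, object$train_ids)
}

#' Residuals of a fitted decoy scorer
#'
#' Score minus normalized LRMSD on the training decoys: positive residuals
#' are decoys scored better than their true quality.
#'
#' @param object An `interpeprank` fit.
#' @param ... Unused.
#' @export
residuals.interpeprank <- function(object, ...) {
  stats::setNames(object$fitted_scores - object$train_lrmsd_norm,
                  object$train_ids)
}

#' Training history plot
#'
#' @param x An `interpeprank` fit.
#' @param ... Passed to `matplot`.
#' @export
plot.interpeprank <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1L, if (x$n_validation > 0) 2L else 1L))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1L, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1L,
                   col = c("black", "firebrick"), bty = "n")
  if (x$n_validation > 0) {
    plot(h$epoch, h$val_spearman, type = "l", xlab = "epoch",
         ylab = "validation Spearman rho")
    graphics::abline(v = x$best_epoch, lty = 3L)
  }
  invisible(x)
}

#' Score decoy graphs with a fitted network
#'
#' @param object An `interpeprank` fit.
#' @param newdata A single `ipr_graph` or a list of them.
#' @param type `"score"` for the probability-weighted score (higher
#'   predicts lower LRMSD), `"probs"` for the bin-probability matrix.
#' @param ... Unused.
#' @return Named numeric vector of scores, or a matrix of bin
#'   probabilities.
#' @export
predict.interpeprank <- function(object, newdata, type = c("score", "probs"), ...) {
  type <- match.arg(type)
  batch <- ipr_batch(newdata)
  fw <- nn_forward(batch, object$weights, object$config, dropout = 0)
  if (type == "probs") {
    rownames(fw$probs) <- batch$id
    fw$probs
  } else {
    stats::setNames(ipr_score_from_probs(fw$probs), batch$id)
  }
}

# ---- ensembles -------------------------------------------------------------

#' Ensemble of trained decoy scorers
#'
#' Members may have different architectures; the ensemble score of a decoy
#' is the arithmetic mean of the member scores.
#'
#' @param ... `interpeprank` fits, or a single list of them.
#' @return Object of class `ipr_ensemble`.
#' @export
ipr_ensemble <- function(...) {
  members <- list(...)
  if (length(members) == 1L && !inherits(members[[1L]], "interpeprank"))
    members <- members[[1L]]
  if (length(members) < 1L) stopf("ensemble needs at least one member")
  ok <- vapply(members, inherits, logical(1L), "interpeprank")
  if (!all(ok)) stopf("all ensemble members must be interpeprank fits")
  structure(list(members = members), class = "ipr_ensemble")
}

#' @export
print.ipr_ensemble <- function(x, ...) {
  cat(sprintf("<ipr_ensemble> %d member network(s)\n", length(x$members)))
  invisible(x)
}

#' @param member_scores Return the per-member score matrix as attribute
#'   `"members"`.
#' @rdname ipr_ensemble
#' @inheritParams predict.interpeprank
#' @param object An `ipr_ensemble`.
#' @export
predict.ipr_ensemble <- function(object, newdata, member_scores = FALSE, ...) {
  sc <- vapply(object$members, function(m) {
    s <- predict(m, newdata)
    if (is.null(dim(s))) s else drop(s)
  }, numeric(if (inherits(newdata, "ipr_graph")) 1L else length(newdata)))
  if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1L)
  out <- rowMeans(sc)
  names(out) <- names(predict(object$members[[1L]], newdata))
  if (member_scores) attr(out, "members") <- sc
  out
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load model checkpoints and ensemble manifests
#'
#' A checkpoint is a serialized fit with its embedded configuration. An
#' ensemble is written as one checkpoint per member plus a TSV manifest
#' (`ensemble.tsv`: columns `member`, `path`) in `dir`.
#'
#' @param object An `interpeprank` fit or `ipr_ensemble`.
#' @param path,dir Destination file / directory.
#' @return The path written, or the loaded object.
#' @export
ipr_save_model <- function(object, path) {
  stopifnot(inherits(object, "interpeprank") || inherits(object, "ipr_ensemble"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname ipr_save_model
#' @export
ipr_load_model <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "interpeprank") && !inherits(obj, "ipr_ensemble"))
    stopf("%s is not an interpeprank checkpoint", path)
  obj
}

#' @rdname ipr_save_model
#' @export
ipr_write_ensemble <- function(object, dir) {
  stopifnot(inherits(object, "ipr_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(object$members), function(k) {
    p <- file.path(dir, sprintf("member_%02d.rds", k))
    ipr_save_model(object$members[[k]], p)
    p
  }, character(1L))
  write_tsv(data.frame(member = seq_along(paths), path = basename(paths)),
            file.path(dir, "ensemble.tsv"))
  invisible(dir)
}

#' @rdname ipr_save_model
#' @export
ipr_read_ensemble <- function(dir) {
  man <- read_tsv(file.path(dir, "ensemble.tsv"))
  ipr_ensemble(lapply(man$path, function(p) ipr_load_model(file.path(dir, p))))
}
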