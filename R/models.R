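# Model-facing API. Three classifier families, one data-frame-first entry
# point: a labeled split tibble goes in, a fitted srp_model comes out, and
# predict()/evaluate_classifier() close the loop.

#' Train the random forest on physicochemical descriptors (RF-PCD)
#'
#' @param x Matrix or data frame of the six physicochemical descriptors.
#' @param y `"ES"`/`"HS"` labels.
#' @param ntree Number of trees (default 500).
#' @param seed Integer seed.
#' @return An object of class `srp_rf` wrapping the fitted forest.
#' @export
train_rf_pcd <- function(x, y, ntree = 500L, seed = 1L) {
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  x <- as.data.frame(x)
  if (all(vapply(x, function(col) length(unique(col)) <= 1L, logical(1L)))) {
    # no informative feature: the forest cannot split (and the library
    # loops trying); fall back to the class prior
    return(structure(list(fit = NULL, prior = mean(y == "ES"), seed = seed),
                     class = "srp_rf"))
  }
  fit <- .with_seed(seed, randomForest::randomForest(
    x = x, y = factor(y, levels = c("HS", "ES")), ntree = ntree
  ))
  structure(list(fit = fit, seed = seed), class = "srp_rf")
}

#' @export
predict.srp_rf <- function(object, newdata, ...) {
  if (is.null(object$fit)) return(rep(object$prior, nrow(as.data.frame(newdata))))
  p <- stats::predict(object$fit, as.data.frame(newdata), type = "prob")
  unname(p[, "ES"])
}

#' @export
print.srp_rf <- function(x, ...) {
  if (is.null(x$fit)) {
    cat("<srp_rf> degenerate fit (constant features), prior ",
        sprintf("%.3f", x$prior), "\n", sep = "")
  } else {
    cat("<srp_rf> ", x$fit$ntree, " trees, OOB error ",
        sprintf("%.3f", utils::tail(x$fit$err.rate[, "OOB"], 1L)), "\n", sep = "")
  }
  invisible(x)
}

.sa_model_types <- c("rf_pcd", "dnn_ecfp", "graphnn")

#' Train a synthetic-accessibility classifier on a labeled split
#'
#' Featurizes the compounds of a split tibble (see [split_dataset()]) with
#' the representation the chosen family needs, trains on the `train` rows
#' using the `validation` rows for checkpoint selection, and returns a
#' fitted model that [predict()] maps from SMILES to ES-probability scores.
#'
#' @param data Labeled split tibble with columns `smiles`, `label`, `split`.
#' @param model `"rf_pcd"` (random forest on physchem descriptors),
#'   `"dnn_ecfp"` (feed-forward net on ECFP4) or `"graphnn"` (communicative
#'   message-passing network on the molecular graph).
#' @param config Named list of family-specific overrides passed through to
#'   [train_rf_pcd()], [train_dnn_ecfp()] or [train_graph_classifier()].
#' @param seed Integer seed.
#' @return An object of class `srp_model`.
#' @export
train_sa_model <- function(data, model = c("rf_pcd", "dnn_ecfp", "graphnn"),
                           config = list(), seed = 1L) {
  model <- match.arg(model)
  stopifnot(all(c("smiles", "label", "split") %in% names(data)))
  tr <- data[data$split == "train", , drop = FALSE]
  va <- data[data$split == "validation", , drop = FALSE]
  if (!nrow(tr) || !nrow(va)) stop("data needs train and validation rows")
  fit <- switch(model,
    rf_pcd = {
      d <- physchem_descriptors(tr$smiles)[, c("mw", "tpsa", "rtb", "hbd",
                                               "hba", "logp")]
      do.call(train_rf_pcd, c(list(x = d, y = tr$label, seed = seed), config))
    },
    dnn_ecfp = {
      do.call(train_dnn_ecfp, c(list(
        x = ecfp4_fingerprint(tr$smiles), y = tr$label,
        x_val = ecfp4_fingerprint(va$smiles), y_val = va$label, seed = seed
      ), config))
    },
    graphnn = {
      mg <- function(s) lapply(featurize(s), `[[`, "molgraph")
      do.call(train_graph_classifier, c(list(
        molgraphs = mg(tr$smiles), y = tr$label,
        molgraphs_val = mg(va$smiles), y_val = va$label, seed = seed
      ), config))
    }
  )
  structure(list(type = model, fit = fit, seed = seed,
                 n_train = nrow(tr), n_validation = nrow(va)),
            class = "srp_model")
}

#' @export
predict.srp_model <- function(object, newdata, ...) {
  smiles <- if (is.character(newdata)) newdata else newdata$smiles
  switch(object$type,
    rf_pcd = predict(object$fit, physchem_descriptors(smiles)[, c(
      "mw", "tpsa", "rtb", "hbd", "hba", "logp")]),
    dnn_ecfp = predict(object$fit, ecfp4_fingerprint(smiles)),
    graphnn = predict(object$fit, lapply(featurize(smiles), `[[`, "molgraph"))
  )
}

#' @export
print.srp_model <- function(x, ...) {
  cat("<srp_model> family ", x$type, ", trained on ", x$n_train,
      " compounds\n", sep = "")
  print(x$fit)
  invisible(x)
}

#' @method glance srp_model
#' @export
glance.srp_model <- function(x, ...) {
  tibble::tibble(
    type = x$type, n_train = x$n_train, n_validation = x$n_validation,
    best_val_auc = if (!is.null(x$fit$best_val_auc)) x$fit$best_val_auc
                   else NA_real_,
    seed = x$seed
  )
}

#' @method tidy srp_model
#' @export
tidy.srp_model <- function(x, ...) {
  if (!is.null(x$fit$history)) return(x$fit$history)
  tibble::tibble(epoch = integer(), train_loss = numeric(),
                 val_auc = numeric(), lr = numeric())
}

#' Training-history curves of a fitted neural model
#'
#' @param object An `srp_model` (or `srp_mlp`/`srp_mpnn`).
#' @param ... Unused.
#' @return A ggplot (empty for the random forest, which has no epochs).
#' @method autoplot srp_model
#' @export
autoplot.srp_model <- function(object, ...) {
  h <- tidy(object)
  if (!nrow(h)) return(ggplot2::ggplot() + ggplot2::theme_void())
  df <- tidyr::pivot_longer(h[, c("epoch", "train_loss", "val_auc")],
                            -"epoch", names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL) +
    ggplot2::theme_minimal()
}
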