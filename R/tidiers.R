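# broom-style accessors for fitted models.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained model: the per-epoch training history
#'
#' @param x An `rda_model`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`,
#'   `train_acc`, `val_loss`, `val_acc`.
#' @method tidy rda_model
#' @export
tidy.rda_model <- function(x, ...) {
  x$history
}

#' One-row model summary
#'
#' @param x An `rda_model`.
#' @param ... Unused.
#' @return Tibble: target, epochs, parameter count, best epoch, best
#'   validation loss, final training/validation loss and accuracy.
#' @method glance rda_model
#' @export
glance.rda_model <- function(x, ...) {
  h <- x$history
  last <- h[nrow(h), ]
  tibble::tibble(target = x$cfg$target,
                 epochs = nrow(h),
                 n_parameters = x$n_parameters,
                 best_epoch = x$best_epoch,
                 best_val_loss = min(h$val_loss),
                 train_loss = last$train_loss,
                 train_acc = last$train_acc,
                 val_loss = last$val_loss,
                 val_acc = last$val_acc)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
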