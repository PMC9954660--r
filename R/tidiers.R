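# broom-style accessors for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fit
#'
#' @param x An `rda_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (epoch, loss, acc, val_loss,
#'   val_acc, attn_min, attn_max).
#' @export
tidy.rda_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x An `rda_fit`.
#' @param ... Unused.
#' @return Tibble with epochs, best epoch, best validation loss/accuracy and
#'   the trainable parameter count.
#' @export
glance.rda_fit <- function(x, ...) {
  hb <- x$history[x$best_epoch, ]
  tibble::tibble(
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    val_loss = hb$val_loss,
    val_acc = hb$val_acc,
    parameters = count_parameters(x$net)$total
  )
}
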