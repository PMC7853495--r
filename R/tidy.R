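# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

tidy_history <- function(fit) {
  if (is.data.frame(fit$history)) return(fit$history)
  # dual fit: two tagged histories
  do.call(rbind, lapply(fit$history, function(h) {
    h2 <- h
    names(h2)[names(h2) == "val_dice"] <- "val_dice_organ"
    h2
  }))
}

#' Tidy the per-epoch training history of a fit
#'
#' @param x An `eitsep_fit`.
#' @param ... Unused.
#' @return A tibble with one row per epoch (per network for a dual fit).
#' @export
tidy.eitsep_fit <- function(x, ...) tibble::as_tibble(tidy_history(x))

#' One-row summary of a fit
#'
#' @param x An `eitsep_fit`.
#' @param ... Unused.
#' @return A one-row tibble: epochs run, final train/validation loss, and
#'   final validation Dice per decoder where available.
#' @export
glance.eitsep_fit <- function(x, ...) {
  h <- tidy_history(x)
  last <- h[nrow(h), ]
  out <- tibble::tibble(
    epochs = max(h$epoch),
    train_loss = last$train_loss,
    val_loss = last$val_loss)
  if ("val_dice_lung" %in% names(h)) {
    out$val_dice_lung <- last$val_dice_lung
    out$val_dice_heart <- last$val_dice_heart
  }
  out$n_parameters <- if (inherits(x, "eitsep_dual_fit")) {
    length(x$weights$lung) + length(x$weights$heart)
  } else {
    length(x$weights)
  }
  out
}

#' Tidy a metrics table
#'
#' @param x An `eitsep_metrics` tibble.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.eitsep_metrics <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
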