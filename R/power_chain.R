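# Generator-to-antenna power budget: cascaded dB losses.

#' One passive component of the transmission chain
#'
#' @param label Free-text component description.
#' @param loss Insertion loss in dB (negative for attenuation).
#' @return An object of class `loss_component`.
#' @export
loss_component <- function(label, loss) {
  stopifnot(is.character(label), length(loss) == 1L, is.finite(loss))
  structure(list(label = label, loss = loss), class = "loss_component")
}

#' Measured/estimated loss chain of the experimental setup
#'
#' The five cable, adapter and connector losses between the generator and
#' the antenna input: 2.5 m Succoform 141, QMA-to-SMA adapter, 0.25 m
#' UT-034, applicator SMA connector, and generator connector. They sum to
#' -2.84 dB, i.e. roughly half the generator setpoint reaches the antenna.
#'
#' @return List of [loss_component()]s.
#' @export
default_loss_chain <- function() {
  list(loss_component("2.5 m Succoform 141 cable (measured)", -1.54),
       loss_component("QMA to SMA adapter (datasheet)", -0.17),
       loss_component("0.25 m UT-034 cable (extrapolated)", -0.73),
       loss_component("applicator SMA connector (estimated)", -0.20),
       loss_component("generator connector (estimated)", -0.20))
}

#' Total loss of a component chain
#'
#' Cascaded passive losses add in dB.
#'
#' @param components List of [loss_component()]s, or a numeric vector of dB
#'   losses. An empty chain is lossless (0 dB).
#' @return Total loss in dB.
#' @export
total_chain_loss <- function(components) {
  if (length(components) == 0L) return(0)
  if (is.numeric(components)) return(sum(components))
  sum(vapply(components, function(x) x$loss, numeric(1)))
}

#' Power delivered to the antenna for a generator setpoint
#'
#' `applied = setpoint * 10^(loss/10)` (power dB convention). A positive
#' "loss" (net gain) is physically implausible in this passive chain and
#' triggers a warning, but the value is still computed.
#'
#' @param setpoint Generator setpoint in W, > 0.
#' @param loss Chain loss in dB (typically negative).
#' @return Applied power in W.
#' @export
applied_power <- function(setpoint, loss) {
  stopifnot(setpoint > 0, is.finite(loss))
  if (loss > 0)
    warning("positive chain loss (net gain) is physically implausible for a passive chain")
  setpoint * 10^(loss / 10)
}
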