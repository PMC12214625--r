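# Base-graphics diagnostics for siting plans.

#' Before/after access scatter for a siting plan
#'
#' Each point is a demand block: x is its access distance before the
#' intervention (existing stores only), y after (opened set). Points on
#' the 1:1 line are unchanged; no point can lie above it, because
#' facilities are only added. Point area scales with block population.
#'
#' @param x a `siting_plan`.
#' @param instance the [access_instance()] the plan was solved on.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, a data.frame of before/after distances per block.
#' @export
plot.siting_plan <- function(x, instance, ...) {
  stopifnot(inherits(instance, "access_instance"))
  before <- nearest_distances(instance)
  after <- nearest_distances(instance, x$opened_sites)
  cex <- 0.4 + 1.6 * sqrt(before$weights / max(before$weights, 1))
  lim <- c(0, max(before$distances))
  graphics::plot(before$distances, after$distances,
                 xlim = lim, ylim = lim, cex = cex,
                 col = grDevices::adjustcolor("steelblue", 0.6), pch = 16,
                 xlab = "access before (m)", ylab = "access after (m)",
                 main = sprintf("%s siting, k = %d",
                                if (x$objective == "ede") "EDE-optimal"
                                else "mean-optimal", x$k), ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  invisible(data.frame(block_id = instance$blocks$block_id,
                       before_m = before$distances,
                       after_m = after$distances))
}
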