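## Disk packing on the honeycomb (triangular) arrangement: the densest
## packing of rigid isotropic disks in the plane. Its packing fraction
## pi * sqrt(3) / 6 ~ 0.9069 bounds how much area rigid disks can cover;
## the ~9% gap fraction is what deformable cells fill when a monolayer
## reaches confluency (packing fraction 1), which is why confluent
## epithelial cells are approximately hexagonal.

#' Honeycomb disk-packing fraction
#'
#' The area fraction covered by unit disks on a triangular lattice with
#' touching neighbors: `pi * sqrt(3) / 6` in closed form, or a Monte-Carlo
#' area estimate over one lattice unit cell.
#'
#' @param method `"closed"` or `"mc"`.
#' @param samples number of Monte-Carlo samples (default 1e6).
#' @param seed RNG seed for the Monte-Carlo estimate.
#' @return Packing fraction in (0, 1).
#' @examples
#' honeycombPackingFraction()           # 0.9069
#' 1 - honeycombPackingFraction()       # gap fraction ~ 0.09
#' @export
honeycombPackingFraction <- function(method = c("closed", "mc"),
                                     samples = 1e6, seed = 1L) {
  method <- match.arg(method)
  if (method == "closed") return(pi * sqrt(3) / 6)
  ## unit cell of the triangular lattice of touching unit disks: the
  ## rhombus spanned by (2, 0) and (1, sqrt(3)), disks of radius 1 at its
  ## four corners
  withSeed(seed, {
    u <- stats::runif(samples)
    v <- stats::runif(samples)
    x <- 2 * u + v
    y <- sqrt(3) * v
    corners <- rbind(c(0, 0), c(2, 0), c(1, sqrt(3)), c(3, sqrt(3)))
    covered <- rep(FALSE, samples)
    for (k in seq_len(nrow(corners))) {
      covered <- covered | ((x - corners[k, 1])^2 + (y - corners[k, 2])^2 < 1)
    }
    mean(covered)
  })
}
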