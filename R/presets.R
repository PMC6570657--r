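# Experimental-condition presets.
#
# The dark preset encodes the dark-adapted disc membrane: three diffusive
# states interpreted as cluster raft / dimer / monomer-like species.
# State occupancies are (0.20, 0.50, 0.30) and every dwell time is 0.100 s
# (order of 100 ms). The two slow diffusion coefficients follow from the
# extended Saffman-Delbrueck relation at the putative species radii
# (90 nm cluster, 2 nm dimer) under the default membrane hydrodynamics;
# the fastest state is set to three times the dimer value, which places
# the ensemble-median short-lag diffusion coefficient inside the
# 0.1-0.6 um^2/s range reported for rhodopsin.

# dark transition matrix: reversible chain, stationary (0.2, 0.5, 0.3),
# all dwell times 0.1 s (3 frames at 30 fps); no direct 1<->3 exchange.
.darkA <- function() {
  matrix(c(2 / 3, 1 / 3, 0,
           2 / 15, 2 / 3, 1 / 5,
           0, 1 / 3, 2 / 3), 3, 3, byrow = TRUE)
}

#' Experimental-condition presets
#'
#' Returns the simulation parameters (diffusive-state model, geometry,
#' acquisition, cluster kinetics) for a named experimental condition:
#' \describe{
#'   \item{dark}{dark-adapted disc: three states with stationary
#'     occupancies (0.20, 0.50, 0.30), dwell times 0.100 s, and diffusion
#'     coefficients from Saffman-Delbrueck sizing (90 nm cluster, 2 nm
#'     dimer, fast state = 3 x dimer).}
#'   \item{light_noGTP}{20\%-photoisomerized disc without GTP: the
#'     slow-state dwell time is tripled (0.300 s), raising its occupancy,
#'     as observed when photoactivated receptor-Gt complexes accumulate.}
#'   \item{dark_MCD}{cholesterol-depleted dark disc: the slow-state dwell
#'     time is halved (0.050 s), lowering cluster occupancy.}
#'   \item{single_state}{one free-diffusion state at the dimer coefficient
#'     (control / supported-bilayer-like).}
#' }
#'
#' @param name preset name.
#' @return a list with elements \code{model}, \code{geometry},
#'   \code{acquisition} and \code{kinetics}.
#' @examples
#' p <- discPreset("dark")
#' stationaryDistribution(p$model)
#' @export
discPreset <- function(name = c("dark", "light_noGTP", "dark_MCD", "single_state")) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown preset '", name[1],
         "'; available: dark, light_noGTP, dark_MCD, single_state"))
  acq <- AcquisitionParams()
  geom <- DiscGeometry("disc", diameter = 8)
  sd <- SDParams()
  dCluster <- sdDiffusion(90e-9, sd)   # slow state: 90-nm cluster raft
  dDimer <- sdDiffusion(2e-9, sd)      # middle state: 2-nm dimer
  kin <- ClusterKinetics(clusterDiffusion = dCluster, clusterRadius = 90e-9,
                         meanLifetime = 0.1)
  if (name == "single_state") {
    model <- DiffusiveStateModel(D = dDimer, transitionMatrix = matrix(1, 1, 1),
                                 initialDistribution = 1)
    return(list(model = model, geometry = geom, acquisition = acq, kinetics = kin))
  }
  A <- .darkA()
  if (name == "light_noGTP") {
    # lengthen state-1 dwell to 0.3 s; exits still go to state 2
    A[1, ] <- c(8 / 9, 1 / 9, 0)
  } else if (name == "dark_MCD") {
    # shorten state-1 dwell to 0.05 s
    A[1, ] <- c(1 / 3, 2 / 3, 0)
  }
  model <- DiffusiveStateModel(D = c(dCluster, dDimer, 3 * dDimer),
                               transitionMatrix = A)
  list(model = model, geometry = geom, acquisition = acq, kinetics = kin)
}
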