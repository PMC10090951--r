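#' Generate synthetic fold-change time-course datasets
#'
#' Simulates the ground-truth circuit (coupled variant for control cells;
#' \code{ymax_tGEF} = 0.1 for GIV-depleted cells) under the standard
#' stimulation protocol, samples the active mGTPase and active tGTPase
#' fold-change traces on experiment-like time grids, and adds independent
#' replicate noise to emulate densitometry / FRET measurements reported as
#' mean +/- SEM over biological replicates. Replicate values are Gaussian
#' with standard deviation \code{noiseScale} times the true value, truncated
#' at 0 (ratio readouts are positive); the baseline point is pinned at fold
#' change 1, as each experimental replicate is normalized to its own
#' baseline.
#'
#' The control mG* trace peaks near 5 min at roughly 3-fold and declines by
#' 30 min; the GIV-depleted mG* trace stays sustained; the tG* traces rise
#' and saturate over the 30-min window.
#'
#' @param params ground-truth [CircuitParameters-class]; default
#'   [defaultCircuitParameters()].
#' @param stimulus stimulus applied from t = 0 (default 0.23).
#' @param gridMG sampling grid (min) for the mG* pulldown-style readout.
#' @param gridTG sampling grid (min) for the tG* FRET-style readout.
#' @param noiseScale replicate noise as a fraction of the trace value
#'   (default 0.1).
#' @param nReplicates biological replicates per point (default 3).
#' @param seed RNG seed.
#' @return list with \code{datasets} (list of four
#'   [TimeCourseDataset-class]: control/GIV-depleted crossed with
#'   mG*/tG*), \code{truth} (the noiseless fold-change traces), and
#'   \code{params} (the ground-truth parameters).
#' @export
syntheticTimecourses <- function(params = defaultCircuitParameters(),
                                 stimulus = 0.23,
                                 gridMG = c(0, 5, 15, 30),
                                 gridTG = seq(0, 30, by = 5),
                                 noiseScale = 0.1, nReplicates = 3L,
                                 seed = 1L) {
  stopifnot(noiseScale >= 0, nReplicates >= 1L)
  set.seed(seed)
  grids <- list(mGstar = gridMG, tGstar = gridTG)
  conditions <- c("control", "giv_depleted")
  datasets <- list()
  truth <- list()
  for (cond in conditions) {
    variant <- .conditionVariant(cond)
    basal <- preEquilibrate(params, variant, "AND", stimulus = 0)
    allT <- sort(unique(c(0, gridMG, gridTG)))
    tc <- simulateCircuit(params, stimulus, variant, "AND",
                          times = allT, init = basal)
    for (readout in names(grids)) {
      tgrid <- grids[[readout]]
      fc <- foldChange(tc, readout)[match(tgrid, tc@time)]
      reps <- matrix(NA_real_, nReplicates, length(tgrid))
      for (r in seq_len(nReplicates)) {
        noisy <- pmax(0, rnorm(length(tgrid), mean = fc,
                               sd = noiseScale * fc))
        noisy[tgrid == 0] <- 1  # each replicate normalized to its baseline
        reps[r, ] <- noisy
      }
      mu <- colMeans(reps)
      sem <- if (nReplicates > 1L) apply(reps, 2L, sd) / sqrt(nReplicates)
             else rep(0, length(tgrid))
      key <- paste(cond, readout, sep = "_")
      datasets[[key]] <- timeCourseDataset(tgrid, mu, sem, cond, readout)
      truth[[key]] <- setNames(fc, tgrid)
    }
  }
  list(datasets = datasets, truth = truth, params = params)
}

#' Generate a PPI fixture graph with a planted linker
#'
#' Builds a random connected interaction graph in which a designated linker
#' node (a GIV stand-in) lies on every geodesic between the anchor seed (an
#' ARF1 stand-in) and a known subset of partner seeds, while longer backup
#' routes through filler nodes keep the graph connected after the linker is
#' deleted. Deleting the linker therefore yields alteration fraction 1
#' exactly for the planted partners, giving network tests a known answer.
#'
#' Layout: the anchor connects to the linker and to a filler chain; planted
#' partners hang off the linker (geodesic length 2 via the linker) and off
#' the end of the filler chain (backup length >= 3); non-planted partners
#' connect directly to the anchor. Combined scores are drawn in [700, 999].
#'
#' @param nNodes total number of nodes (>= nSeeds + 3).
#' @param nSeeds number of seed proteins including the anchor (>= 3).
#' @param seed RNG seed.
#' @param cutoff score cutoff recorded on the returned graph.
#' @return list with \code{graph} (an [InteractionGraph-class]),
#'   \code{anchor}, \code{linker}, \code{plantedPartners} (partners whose
#'   anchor-pair geodesics all traverse the linker), and \code{edges} (the
#'   raw edge table).
#' @export
generatePPIFixture <- function(nNodes, nSeeds, seed = 1L, cutoff = 667) {
  if (nSeeds < 3L) stop("infeasible size: nSeeds must be >= 3")
  if (nSeeds > nNodes) stop("infeasible size: nSeeds exceeds nNodes")
  if (nNodes < nSeeds + 3L)
    stop("infeasible size: need nNodes >= nSeeds + 3 (linker and fillers)")
  set.seed(seed)
  anchor <- "ARF1"
  linker <- "GIV"
  partners <- sprintf("SEED%02d", seq_len(nSeeds - 1L))
  nFill <- nNodes - 1L - 1L - length(partners)
  fillers <- sprintf("FILL%02d", seq_len(nFill))
  nPlanted <- max(1L, min(length(partners),
                          ceiling(length(partners) / 2L)))
  planted <- sort(sample(partners, nPlanted))
  direct <- setdiff(partners, planted)
  edge <- function(a, b) data.frame(protein1 = a, protein2 = b)
  edges <- rbind(
    edge(anchor, linker),
    edge(anchor, fillers[1L]),
    if (nFill > 1L)
      do.call(rbind, lapply(seq_len(nFill - 1L), function(i)
        edge(fillers[i], fillers[i + 1L]))),
    do.call(rbind, lapply(planted, function(pt)
      rbind(edge(linker, pt), edge(fillers[nFill], pt)))),
    if (length(direct))
      do.call(rbind, lapply(direct, function(pt) edge(anchor, pt)))
  )
  edges$combined_score <- sample(700:999, nrow(edges), replace = TRUE)
  ig <- loadInteractions(edges, cutoff = cutoff,
                         seeds = c(anchor, partners))
  list(graph = ig, anchor = anchor, linker = linker,
       plantedPartners = planted, edges = edges)
}
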