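# Synthetic-data generator: plants a signed sparse TF-target network, smooth
# TF activity trajectories (optionally bifurcating), and realizes them as
# negative-binomial counts under a two-ecotype treated/control replicated
# time-course design, together with ortholog/GO validation fixtures.

#' Build a simulation configuration
#'
#' The defaults encode the simulated study conditions: two ecotypes, six
#' time points with three biological replicates of treated and matched
#' control samples, a sparse signed TF-target network with weights of
#' magnitude 0.5-2, NB dispersion 0.05, and a planted trajectory
#' bifurcation. See the methods vignette for the rationale behind each
#' value.
#'
#' @param nTfs,nTgs numbers of TFs and target genes.
#' @param nTimepoints time points per ecotype (study designs use 6 or 8).
#' @param nReplicates biological replicates (>= 2).
#' @param nEcotypes independently parameterized ecotypes sharing the gene
#'   universe and the planted network.
#' @param nHousekeeping spike-in genes with condition-independent means.
#' @param edgeDensity TF-target edge probability.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2); 0 gives
#'   Poisson counts.
#' @param librarySizeRange min/max sequencing depth per sample.
#' @param bifurcationTime 1-based time index at which planted trajectories
#'   diverge, or NA for none.
#' @param seed master seed; every generator routine derives its own
#'   sub-stream from it.
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nTfs = 5L, nTgs = 80L, nTimepoints = 6L,
                             nReplicates = 3L, nEcotypes = 2L,
                             nHousekeeping = 10L, edgeDensity = 0.06,
                             dispersion = 0.05,
                             librarySizeRange = c(3e5, 5e5),
                             bifurcationTime = 3L, seed = 1L) {
  methods::new("SimulationConfig",
    nTfs = as.integer(nTfs), nTgs = as.integer(nTgs),
    nTimepoints = as.integer(nTimepoints),
    nReplicates = as.integer(nReplicates),
    nEcotypes = as.integer(nEcotypes),
    nHousekeeping = as.integer(nHousekeeping),
    edgeDensity = edgeDensity, dispersion = dispersion,
    librarySizeRange = as.numeric(librarySizeRange),
    bifurcationTime = as.integer(bifurcationTime),
    seed = as.integer(seed))
}

.tfNames <- function(n) sprintf("TF%02d", seq_len(n))
.tgNames <- function(n) sprintf("G%03d", seq_len(n))

#' Generate a planted connectivity matrix
#'
#' Draws a sparse binary support at the configured density, repairs it so
#' every TF has at least two targets, and regenerates until the NCA
#' identifiability criteria hold (bounded attempts). Edge weights are
#' drawn from +/- Uniform(0.5, 2). Deterministic given the config seed.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param maxAttempts attempts before giving up with an error.
#' @return a \linkS4class{ConnectivityMatrix} (targets x TFs).
#' @export
generateNetwork <- function(cfg, maxAttempts = 200L) {
  stopifnot(methods::is(cfg, "SimulationConfig"))
  .withSeed(.subSeed(cfg@seed, 1L), {
    tfs <- .tfNames(cfg@nTfs); tgs <- .tgNames(cfg@nTgs)
    for (attempt in seq_len(maxAttempts)) {
      supp <- matrix(runif(cfg@nTgs * cfg@nTfs) < cfg@edgeDensity,
                     cfg@nTgs, cfg@nTfs, dimnames = list(tgs, tfs))
      minTargets <- min(3L, cfg@nTgs)    # repair: >= 2 required, 3 planted
      for (j in seq_len(cfg@nTfs)) {     # for robustness to edge losses
        while (sum(supp[, j]) < minTargets)
          supp[sample.int(cfg@nTgs, 1L), j] <- TRUE
      }
      if (checkIdentifiability(supp)$pass) {
        w <- matrix(0, cfg@nTgs, cfg@nTfs, dimnames = list(tgs, tfs))
        ne <- sum(supp)
        w[supp] <- sample(c(-1, 1), ne, replace = TRUE) * runif(ne, 0.5, 2)
        return(methods::new("ConnectivityMatrix", weights = w))
      }
    }
    stop("no identifiable topology found in ", maxAttempts, " attempts; ",
         "raise edgeDensity or nTgs")
  })
}

#' Generate planted TF activity trajectories
#'
#' Per ecotype, each TF's activity over the time points is a smooth curve:
#' a discrete-cosine mode specific to the TF (so distinct TFs are
#' decorrelated by construction) plus a small random low-order polynomial,
#' rescaled to an amplitude of roughly 2-2.8 sd. When a bifurcation
#' time is configured, the first two TFs become branch drivers: their
#' activities coincide exactly before the bifurcation index and diverge
#' from it onward (+/- the divergence offset plus independent smooth
#' wiggle), so the two planted gene groups are driven apart from that
#' time point on while remaining only weakly correlated overall.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param network the planted \linkS4class{ConnectivityMatrix} (defines
#'   the TF set).
#' @return list with elements tfa (list of \linkS4class{TFAMatrix} per
#'   ecotype, columns = time points), tfGroups (named integer vector:
#'   1 and 2 for the branch drivers, 0 for the rest; all 0 when no
#'   bifurcation) and divergence (the planted between-group offset per
#'   time point).
#' @export
generateTfa <- function(cfg, network) {
  tfs <- tfIds(network)
  n <- length(tfs); T <- cfg@nTimepoints
  bt <- cfg@bifurcationTime
  if (!is.na(bt) && n < 2L)
    stop("a planted bifurcation needs at least two TFs")
  .withSeed(.subSeed(cfg@seed, 2L), {
    tfGroups <- setNames(rep(0L, n), tfs)
    if (!is.na(bt)) tfGroups[1:2] <- c(1L, 2L)
    tt <- seq(0, 1, length.out = T)
    # discrete-cosine modes: mutually orthogonal over the time grid, so
    # TFs with distinct dominant modes stay decorrelated by construction
    idx <- seq_len(T)
    B <- vapply(seq_len(T - 1L), function(k) {
      b <- cos(pi * k * (idx - 0.5) / T)
      b / sd(b)
    }, numeric(T))
    modeOf <- ((seq_len(n) - 1L) %% (T - 1L)) + 1L
    smoothCurve <- function(mode, amp) {
      u <- B[, mode] +
        runif(1, -0.3, 0.3) * (tt - 0.5) * 2 +
        runif(1, -0.3, 0.3) * ((tt - 0.5)^2 - 1 / 12) * 4
      sample(c(-1, 1), 1L) * u / sd(u) * amp
    }
    div <- rep(0, T)
    if (!is.na(bt)) div[bt:T] <- 1.6
    tfaList <- vector("list", cfg@nEcotypes)
    for (e in seq_len(cfg@nEcotypes)) {
      U <- matrix(0, n, T, dimnames = list(tfs, sprintf("t%d", seq_len(T))))
      for (i in seq_len(n))
        U[i, ] <- smoothCurve(modeOf[i], runif(1, 2.0, 2.8))
      if (!is.na(bt)) {
        shared <- smoothCurve(1L, 1.0)
        for (g in 1:2) {
          eps <- smoothCurve(modeOf[g], 0.8)
          p <- numeric(T)
          p[seq_len(bt - 1L)] <- shared[seq_len(bt - 1L)]
          p[bt:T] <- eps[bt:T] + (if (g == 1L) div[bt:T] else -div[bt:T])
          U[g, ] <- p
        }
      }
      tfaList[[e]] <- methods::new("TFAMatrix", activities = U)
    }
    names(tfaList) <- sprintf("E%d", seq_len(cfg@nEcotypes))
    list(tfa = tfaList, tfGroups = tfGroups, divergence = 2 * div)
  })
}

# assign regulated targets whose dominant regulator is a branch driver to
# that driver's branch (sign-aware); other regulated targets get 0
.tgGroups <- function(network, tfGroups) {
  w <- controlStrengths(network)
  reg <- rowSums(w != 0) > 0
  out <- integer(0)
  for (g in rownames(w)[reg]) {
    j <- which.max(abs(w[g, ]))
    grp <- unname(tfGroups[colnames(w)[j]])
    if (grp > 0L && w[g, j] < 0) grp <- 3L - grp
    out[g] <- grp
  }
  out
}

#' Realize planted structure as NB counts
#'
#' For each sample, the planted log2-scale signal for a target gene is the
#' corresponding entry of A P (its TF column for TFs tracking their own
#' activity; zero for housekeeping spike-ins and all control samples).
#' Signals are clipped to +/- 8 (overflow guard), added to per-gene
#' baselines, converted to relative abundances, scaled to a per-sample
#' library size, and drawn as NB counts with shared dispersion phi
#' (variance = mu + phi mu^2; Poisson when phi = 0). Two always-zero
#' "silent" genes are planted to exercise the expression filter.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param network the planted \linkS4class{ConnectivityMatrix}.
#' @param tfa result of \code{\link{generateTfa}}.
#' @return list with elements se (a SummarizedExperiment from
#'   \code{\link{stressCountSet}}) and truth (a
#'   \linkS4class{GroundTruth}).
#' @export
generateCounts <- function(cfg, network, tfa) {
  w <- controlStrengths(network)
  tfs <- colnames(w); tgs <- rownames(w)
  hks <- if (cfg@nHousekeeping) sprintf("HK%02d", seq_len(cfg@nHousekeeping))
         else character()
  silent <- c("SILENT1", "SILENT2")
  genes <- c(tfs, tgs, hks, silent)
  T <- cfg@nTimepoints; R <- cfg@nReplicates
  ecos <- names(tfa$tfa)
  .withSeed(.subSeed(cfg@seed, 3L), {
    baseline <- runif(length(genes), 4, 9)
    names(baseline) <- genes
    meta <- expand.grid(replicate = seq_len(R), time = seq_len(T),
                        condition = c("treated", "control"), ecotype = ecos,
                        stringsAsFactors = FALSE)
    meta$sample_id <- with(meta, sprintf("%s_%s_t%d_r%d", ecotype,
                                         substr(condition, 1, 3), time,
                                         replicate))
    counts <- matrix(0L, length(genes), nrow(meta),
                     dimnames = list(genes, meta$sample_id))
    for (s in seq_len(nrow(meta))) {
      P <- activities(tfa$tfa[[meta$ecotype[s]]])
      z <- setNames(numeric(length(genes)), genes)
      if (meta$condition[s] == "treated") {
        pt <- P[, meta$time[s]]
        z[tfs] <- pt
        z[tgs] <- as.numeric(w %*% pt)
      }
      z <- pmin(pmax(z, -8), 8)
      rel <- 2^(baseline + z)
      rel[silent] <- 0
      L <- runif(1, cfg@librarySizeRange[1], cfg@librarySizeRange[2])
      mu <- L * rel / sum(rel)
      counts[, s] <- if (cfg@dispersion == 0) rpois(length(mu), mu)
                     else rnbinom(length(mu), size = 1 / cfg@dispersion,
                                  mu = mu)
    }
    se <- stressCountSet(counts, meta)
    S4Vectors::metadata(se)$tfs <- tfs
    planted <- which(w != 0, arr.ind = TRUE)
    orthologTruth <- data.frame(tf = tfs[planted[, 2L]],
                                tg = tgs[planted[, 1L]],
                                stringsAsFactors = FALSE)
    orthologTruth <- orthologTruth[order(orthologTruth$tf,
                                         orthologTruth$tg), ]
    rownames(orthologTruth) <- NULL
    truth <- methods::new("GroundTruth",
      connectivity = network,
      tfa = tfa$tfa,
      bifurcation = list(time = cfg@bifurcationTime,
                         tfGroups = tfa$tfGroups,
                         tgGroups = .tgGroups(network, tfa$tfGroups),
                         divergence = tfa$divergence),
      orthologTruth = orthologTruth,
      goTruth = list())
    list(se = se, truth = truth)
  })
}

#' Generate ortholog and GO validation fixtures
#'
#' Builds (i) an ortholog map linking a \code{transferFraction} subset of
#' the planted genes to synthetic reference-species genes, (ii) reference
#' TF-TG interaction sets containing exactly the images of the planted
#' edges whose endpoints are both mapped (plus optional random decoy
#' pairs), and (iii) a three-level rooted GO DAG in which each TF's true
#' targets are annotated inside a TF-specific clade while background genes
#' are annotated uniformly across leaves.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param truth the \linkS4class{GroundTruth} from
#'   \code{\link{generateCounts}}.
#' @param transferFraction fraction of planted genes given an ortholog.
#' @param nDecoys random non-edge reference pairs added per source.
#' @return list with elements orthologMap, referenceSets (data.frames),
#'   goDag (a \linkS4class{GoDag}), annotations (data.frame gene, go_id,
#'   aspect) and truth (the input with orthologTruth restricted to
#'   transferable edges and goTruth filled in).
#' @export
generateValidationFixtures <- function(cfg, truth, transferFraction = 1,
                                       nDecoys = 0L) {
  stopifnot(transferFraction >= 0, transferFraction <= 1)
  w <- controlStrengths(truth@connectivity)
  tfs <- colnames(w); tgs <- rownames(w)
  edges <- truth@orthologTruth
  if (!nrow(edges)) {
    planted <- which(w != 0, arr.ind = TRUE)
    edges <- data.frame(tf = tfs[planted[, 2L]], tg = tgs[planted[, 1L]])
  }
  .withSeed(.subSeed(cfg@seed, 4L), {
    refName <- function(g) if (length(g)) paste0("ref_", g) else character()
    inNet <- sort(unique(c(edges$tf, edges$tg)))
    nMap <- floor(transferFraction * length(inNet))
    mapped <- sort(sample(inNet, nMap))
    orthologMap <- data.frame(
      query_gene = mapped, ref_species = rep("refspecies", length(mapped)),
      ref_gene = refName(mapped),
      group_id = sprintf("OG%04d", seq_along(mapped)),
      stringsAsFactors = FALSE)
    transferable <- edges[edges$tf %in% mapped & edges$tg %in% mapped, ,
                          drop = FALSE]
    rownames(transferable) <- NULL
    sources <- c("refdb1", "refdb2")
    refs <- data.frame(
      source = rep(sources, length.out = nrow(transferable)),
      ref_species = rep("refspecies", nrow(transferable)),
      tf = refName(transferable$tf),
      target = refName(transferable$tg),
      stringsAsFactors = FALSE)
    if (nDecoys > 0L && length(mapped) > 1L) {
      pool <- expand.grid(tf = intersect(tfs, mapped),
                          tg = intersect(tgs, mapped),
                          stringsAsFactors = FALSE)
      key <- paste(pool$tf, pool$tg)
      pool <- pool[!key %in% paste(edges$tf, edges$tg), , drop = FALSE]
      take <- pool[sample.int(nrow(pool), min(nDecoys, nrow(pool))), ,
                   drop = FALSE]
      refs <- rbind(refs, data.frame(
        source = rep(sources, length.out = nrow(take)),
        ref_species = "refspecies",
        tf = paste0("ref_", take$tf), target = paste0("ref_", take$tg)))
    }
    # GO DAG: root -> one clade per TF + a background clade -> 2 leaves each
    root <- "GO:0008150"
    clades <- sprintf("GO:10000%02d", seq_along(tfs))
    bgClade <- "GO:2000000"
    leaves <- c(vapply(seq_along(tfs), function(i)
      sprintf("GO:11%02d%03d", i, 1:2), character(2)))
    bgLeaves <- sprintf("GO:21000%02d", 1:4)
    terms <- data.frame(
      id = c(root, clades, bgClade, leaves, bgLeaves),
      name = c("biological_process",
               paste("regulon program", tfs), "background process",
               paste("regulon leaf", rep(tfs, each = 2), 1:2),
               paste("background leaf", 1:4)),
      stringsAsFactors = FALSE)
    dagEdges <- rbind(
      data.frame(child = c(clades, bgClade), parent = root, type = "is_a"),
      data.frame(child = leaves, parent = rep(clades, each = 2),
                 type = rep(c("is_a", "part_of"), length(clades))),
      data.frame(child = bgLeaves, parent = bgClade, type = "is_a"))
    dag <- goDag(terms, dagEdges)
    # annotations: true targets to their TF's clade leaves, rest uniform
    tgGroupsTf <- vapply(tgs, function(g) {
      if (any(w[g, ] != 0)) colnames(w)[which.max(abs(w[g, ]))]
      else NA_character_
    }, character(1))
    ann <- list()
    goTruth <- list()
    for (i in seq_along(tfs)) {
      mine <- names(tgGroupsTf)[!is.na(tgGroupsTf) & tgGroupsTf == tfs[i]]
      cladeLeaves <- leaves[(2 * i - 1):(2 * i)]
      goTruth[[tfs[i]]] <- clades[i]
      if (length(mine))
        ann[[length(ann) + 1L]] <- data.frame(
          gene = mine, go_id = rep(cladeLeaves, length.out = length(mine)),
          stringsAsFactors = FALSE)
    }
    annotated <- unlist(lapply(ann, `[[`, "gene"))
    rest <- setdiff(c(tfs, tgs), annotated)
    allLeaves <- c(leaves, bgLeaves)
    if (length(rest))
      ann[[length(ann) + 1L]] <- data.frame(
        gene = rest, go_id = sample(allLeaves, length(rest), replace = TRUE),
        stringsAsFactors = FALSE)
    annotations <- do.call(rbind, ann)
    annotations <- annotations[order(annotations$gene, annotations$go_id), ]
    annotations$aspect <- "BP"
    rownames(annotations) <- NULL
    truth@orthologTruth <- transferable
    truth@goTruth <- goTruth
    list(orthologMap = orthologMap, referenceSets = refs, goDag = dag,
         annotations = annotations, truth = truth)
  })
}

#' Run the full generator
#'
#' Convenience wrapper: network, activities, counts and validation
#' fixtures from one config.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param transferFraction,nDecoys passed to
#'   \code{\link{generateValidationFixtures}}.
#' @return list with elements se, truth, network, tfa, orthologMap,
#'   referenceSets, goDag, annotations.
#' @export
simulateStudy <- function(cfg = simulationConfig(), transferFraction = 1,
                          nDecoys = 0L) {
  network <- generateNetwork(cfg)
  tfa <- generateTfa(cfg, network)
  cnt <- generateCounts(cfg, network, tfa)
  fix <- generateValidationFixtures(cfg, cnt$truth, transferFraction,
                                    nDecoys)
  list(se = cnt$se, truth = fix$truth, network = network, tfa = tfa,
       orthologMap = fix$orthologMap, referenceSets = fix$referenceSets,
       goDag = fix$goDag, annotations = fix$annotations)
}

#' Planted bifurcating trajectory fixture
#'
#' Builds a log2-fold-change trajectory matrix directly from the planted
#' branch trajectories: genes are assigned alternately to the two groups,
#' each gene's trajectory is its group's mean activity trajectory plus iid
#' Gaussian noise, and an artificial zero column is prepended at t0.
#' Useful for testing temporal-map recovery under controlled separation.
#'
#' @param truth a \linkS4class{GroundTruth} with a planted bifurcation.
#' @param nGenes number of genes to simulate.
#' @param noiseSd emission noise sd (the planted between-group divergence
#'   is \code{truth@bifurcation$divergence}).
#' @param seed RNG seed.
#' @return list with elements values (genes x (T+1) matrix, first column
#'   t0 = 0) and groups (named integer vector of planted branches).
#' @export
bifurcationTrajectories <- function(truth, nGenes = 120L, noiseSd = 0.35,
                                    seed = 1L) {
  bt <- truth@bifurcation$time
  if (is.na(bt)) stop("ground truth has no planted bifurcation")
  P <- activities(truth@tfa[[1L]])
  gr <- truth@bifurcation$tfGroups
  m1 <- colMeans(P[names(gr)[gr == 1L], , drop = FALSE])
  m2 <- colMeans(P[names(gr)[gr == 2L], , drop = FALSE])
  T <- ncol(P)
  .withSeed(seed, {
    groups <- rep(c(1L, 2L), length.out = nGenes)
    names(groups) <- sprintf("sim%03d", seq_len(nGenes))
    vals <- matrix(0, nGenes, T + 1L,
                   dimnames = list(names(groups),
                                   c("t0", sprintf("t%d", seq_len(T)))))
    for (i in seq_len(nGenes)) {
      mu <- if (groups[i] == 1L) m1 else m2
      vals[i, -1L] <- mu + rnorm(T, 0, noiseSd)
    }
    list(values = vals, groups = groups)
  })
}
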