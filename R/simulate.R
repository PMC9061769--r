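# Synthetic AMD-like virus-host communities with a machine-readable truth
# table: host genomes carrying prophages and CRISPR arrays, viral genome
# clusters at controlled divergence, lognormal abundances with planted
# lineage-specific virus-host abundance ratios, a latitudinal richness
# gradient, spatial distance decay, and metadata generated from a known
# recursive path model.

.amdPhylaPool <- c("Proteobacteria", "Thermoplasmatota", "Actinobacteriota",
                   "Acidobacteriota", "Chloroflexota", "Micrarchaeota",
                   "Nitrospirota", "Elusimicrobiota")

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic community generator. All
#' sequence, ecology and metadata structure is derived deterministically
#' from `seed`.
#'
#' @param seed Integer master seed.
#' @param n_sites Number of geographically distinct sites.
#' @param samples_per_site Samples per site (jittered within
#'   `site_jitter_km`).
#' @param n_host_phyla,hosts_per_phylum Host community layout; host
#'   populations within a phylum are ranked from common specialists to rare
#'   generalists.
#' @param viruses_per_host Viral clusters planted per host population.
#' @param genome_length_range Viral genome length bounds, bp (min >= 10 kb,
#'   the standard viral size floor).
#' @param divergence_levels Per-site substitution probabilities for the
#'   mutated copies in each viral cluster; expected pairwise ANI to the
#'   cluster ancestor is 100 x (1 - divergence). In [0, 0.5); 0 plants an
#'   identical duplicate.
#' @param planted_vhr Positive virus-host abundance ratio per phylum
#'   (recycled/truncated to `n_host_phyla`); default spans ~2-13,
#'   mirroring the typically-above-one lineage VHRs seen in AMD sediment
#'   communities.
#' @param prophage_fraction,crispr_fraction Probability that a host
#'   population's primary viral cluster is planted as a prophage /
#'   that the host carries a CRISPR array targeting it.
#' @param ddr_slope Target distance-decay slope (Bray-Curtis similarity per
#'   log10 km); the spatial kernel is calibrated numerically against it and
#'   the realized noise-free slope is stored in the truth table.
#' @param lat_richness_gradient Host populations lost per degree of
#'   latitude away from the equatorward edge of the sampled range.
#' @param path_coefficients A `"pathSpec"` with planted coefficients for
#'   the metadata-generating structural equations (default
#'   [examplePathSpec()]).
#' @param noise_sd Lognormal noise (sd on the natural-log scale) applied to
#'   abundances; 0 gives the noise-free limit.
#' @param n_background_viruses Unlinked background viral clusters.
#' @param members_per_host_population Genomes (MAG replicates) per host
#'   population.
#' @param lat_range,lon_range Site coordinate bounds, decimal degrees
#'   (default spans the mining belt of Southern China).
#' @param site_jitter_km Within-site sample dispersion (exposed as a free
#'   parameter; field surveys rarely report it).
#' @param homology_segment_bp Length of the planted shared-genome segment
#'   behind homology evidence (>= 2.5 kb so the standard linkage filter can
#'   see it).
#' @param virulent_prob_range Per-phylum probability range that a viral
#'   cluster is virulent (increasing across phyla, planting a lifestyle
#'   trend along the abundance-response gradient).
#' @return A validated list of class `"simConfig"`.
#' @export
simConfig <- function(seed = 1L,
                      n_sites = 6L,
                      samples_per_site = 5L,
                      n_host_phyla = 4L,
                      hosts_per_phylum = 5L,
                      viruses_per_host = 1L,
                      genome_length_range = c(10000L, 14000L),
                      divergence_levels = c(0.03, 0.10),
                      planted_vhr = NULL,
                      prophage_fraction = 0.5,
                      crispr_fraction = 0.5,
                      ddr_slope = -0.10,
                      lat_richness_gradient = 1,
                      path_coefficients = examplePathSpec(),
                      noise_sd = 0.3,
                      n_background_viruses = 3L,
                      members_per_host_population = 2L,
                      lat_range = c(23, 32),
                      lon_range = c(106, 118),
                      site_jitter_km = 0.4,
                      homology_segment_bp = 3000L,
                      virulent_prob_range = c(0.2, 0.8)) {
  if (genome_length_range[1L] < 10000)
    stop("configuration error: genome_length_range minimum must be >= 10000 bp")
  if (any(divergence_levels < 0) || any(divergence_levels >= 0.5))
    stop("divergence levels must be in [0, 0.5)")
  if (any(divergence_levels > 0.4))
    warning("divergence > 0.4 approaches background identity; ",
            "clusters may be indistinguishable")
  for (p in c(prophage_fraction, crispr_fraction))
    if (p < 0 || p > 1) stop("fractions must be proportions in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.null(planted_vhr))
    planted_vhr <- 10^seq(0.3, 1.1, length.out = n_host_phyla)
  planted_vhr <- rep_len(planted_vhr, n_host_phyla)
  if (any(planted_vhr <= 0)) stop("planted VHRs must be positive")
  if (!inherits(path_coefficients, "pathSpec"))
    stop("path_coefficients must be a pathSpec (see readPathSpec)")
  phyla <- c(.amdPhylaPool,
             sprintf("NovelPhylum%02d", seq_len(max(0, n_host_phyla - 8))))
  structure(list(
    seed = as.integer(seed), n_sites = as.integer(n_sites),
    samples_per_site = as.integer(samples_per_site),
    n_host_phyla = as.integer(n_host_phyla),
    hosts_per_phylum = as.integer(hosts_per_phylum),
    viruses_per_host = as.integer(viruses_per_host),
    genome_length_range = as.integer(genome_length_range),
    divergence_levels = divergence_levels,
    planted_vhr = stats::setNames(planted_vhr, phyla[seq_len(n_host_phyla)]),
    prophage_fraction = prophage_fraction,
    crispr_fraction = crispr_fraction,
    ddr_slope = ddr_slope,
    lat_richness_gradient = lat_richness_gradient,
    path_coefficients = path_coefficients,
    noise_sd = noise_sd,
    n_background_viruses = as.integer(n_background_viruses),
    members_per_host_population = as.integer(members_per_host_population),
    lat_range = lat_range, lon_range = lon_range,
    site_jitter_km = site_jitter_km,
    homology_segment_bp = as.integer(homology_segment_bp),
    virulent_prob_range = virulent_prob_range,
    phyla = phyla[seq_len(n_host_phyla)]), class = "simConfig")
}

# Count planted substitutions falling in a 0-based half-open window.
.subsInWindow <- function(positions, start0, end0) {
  sum(positions > start0 & positions <= end0)
}

#' Simulate genomes: hosts with prophages and CRISPR arrays, viral clusters
#'
#' Generates host genomes (a configurable fraction carrying an embedded
#' prophage copy of their virus at recorded coordinates, and/or a CRISPR
#' array whose spacers copy viral segments exactly) and viral genome
#' clusters (a random ancestor plus one mutated copy per divergence level,
#' so expected pairwise ANI to the ancestor is 100 x (1 - divergence)).
#' The truth table records intended vOTU membership — copies diverged past
#' the 95% ANI species threshold are their own populations — and every
#' planted evidence-defined virus-host link, derived from the generator's
#' own substitution bookkeeping.
#'
#' @param config A [simConfig()].
#' @return List of class `"simSequences"`: `viruses` and `hosts`
#'   ([Biostrings::DNAStringSet] with provenance/quality metadata columns),
#'   `scaffoldToGenome` binning map, `taxonomy` (host genome -> phylum),
#'   `spacers` (planted spacer table), and `truth` (vOTU and host
#'   population membership, representatives, phylum map, links with
#'   evidence, lifestyles, planted VHRs, prophage coordinates).
#' @export
simulateSequences <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  withSeed(deriveSeed(config$seed, "sequences"), {
    P <- config$n_host_phyla
    HPP <- config$hosts_per_phylum
    VPH <- config$viruses_per_host
    lenR <- config$genome_length_range
    segBp <- config$homology_segment_bp
    phyla <- config$phyla
    virProb <- seq(config$virulent_prob_range[1L],
                   config$virulent_prob_range[2L], length.out = P)

    hostSeqs <- list(); hostMeta <- list()
    virSeqs <- list(); virMeta <- list()
    votu <- character(0)        # genome -> votu label
    hostMember <- character(0)  # genome -> host population id
    hostRep <- character(0)     # host population -> representative genome
    phylumMap <- character(0)   # representative genome -> phylum
    lifestyles <- character(0)  # votu label -> lifestyle
    linksTruth <- list()
    prophages <- list()
    spacersTruth <- list()
    clusterInfo <- list()       # per viral cluster: members, subs positions

    # --- viral clusters -------------------------------------------------
    makeCluster <- function(clId, lifestyle) {
      L <- sample(seq(lenR[1L], lenR[2L]), 1L)
      anc <- randomDna(L)
      ids <- paste0(clId, "_g00")
      seqs <- list(anc)
      subs <- list(integer(0))
      labels <- ids  # votu label per member
      for (k in seq_along(config$divergence_levels)) {
        d <- config$divergence_levels[k]
        mut <- mutateSequence(anc, d)
        id <- sprintf("%s_g%02d", clId, k)
        ids <- c(ids, id)
        seqs <- c(seqs, mut$seq)
        subs <- c(subs, list(mut$positions))
        labels <- c(labels,
                    if (100 * (1 - d) >= 95) ids[1L] else id)
      }
      list(id = clId, ancestor = ids[1L], members = ids, seqs = seqs,
           subs = subs, labels = labels, length = L, lifestyle = lifestyle)
    }

    clusters <- list()
    for (ph in seq_len(P)) {
      for (i in seq_len(HPP)) {
        for (v in seq_len(VPH)) {
          clId <- sprintf("v_%s_r%02d_%d", phyla[ph], i, v)
          lf <- if (stats::runif(1) < virProb[ph]) "virulent" else "temperate"
          clusters[[clId]] <- makeCluster(clId, lf)
        }
      }
    }
    for (b in seq_len(config$n_background_viruses)) {
      clId <- sprintf("v_bg_%02d", b)
      lf <- if (stats::runif(1) < 0.5) "virulent" else "temperate"
      clusters[[clId]] <- makeCluster(clId, lf)
    }

    # --- planned links (cluster -> host population) ---------------------
    # primary one-to-one pairs; nested within-phylum generalism for the
    # first cluster of each rank; cross-phylum links for top-rank viruses
    hpopId <- function(ph, i) sprintf("h_%s_r%02d", phyla[ph], i)
    plan <- list()
    for (ph in seq_len(P)) {
      for (i in seq_len(HPP)) {
        for (v in seq_len(VPH)) {
          clId <- sprintf("v_%s_r%02d_%d", phyla[ph], i, v)
          plan[[length(plan) + 1L]] <- list(
            cluster = clId, hpop = hpopId(ph, i), primary = TRUE)
          if (v == 1L && i > 1L) {
            for (j in seq_len(i - 1L)) {
              plan[[length(plan) + 1L]] <- list(
                cluster = clId, hpop = hpopId(ph, j), primary = FALSE)
            }
          }
        }
      }
      if (HPP >= 3L) {
        top <- sprintf("v_%s_r%02d_1", phyla[ph], HPP)
        for (ph2 in setdiff(seq_len(P), ph)) {
          plan[[length(plan) + 1L]] <- list(
            cluster = top, hpop = hpopId(ph2, 1L), primary = FALSE)
        }
      }
    }

    # evidence assignment (per primary pair)
    planDf <- do.call(rbind, lapply(plan, as.data.frame))
    planDf$prophage <- FALSE
    planDf$crispr <- FALSE
    pri <- which(planDf$primary)
    planDf$prophage[pri] <- stats::runif(length(pri)) < config$prophage_fraction
    planDf$crispr[pri] <- stats::runif(length(pri)) < config$crispr_fraction
    # one prophage per viral cluster at most (a provirus has one source)
    dupPro <- duplicated(planDf$cluster) & planDf$prophage
    planDf$prophage[dupPro] <- FALSE

    # --- host genomes with inserts --------------------------------------
    for (ph in seq_len(P)) {
      for (i in seq_len(HPP)) {
        hp <- hpopId(ph, i)
        L <- sample(seq(lenR[1L], lenR[2L]), 1L)
        backbone <- randomDna(L)
        g1 <- paste0(hp, "_g1")
        rows <- which(planDf$hpop == hp)

        inserts <- list()
        for (r in rows) {
          cl <- clusters[[planDf$cluster[r]]]
          if (planDf$prophage[r]) {
            inserts[[length(inserts) + 1L]] <- list(
              kind = "prophage", cluster = cl$id, seq = cl$seqs[[1L]],
              vstart = 0L, vend = cl$length)
          } else {
            a <- sample(seq_len(cl$length - segBp), 1L)
            inserts[[length(inserts) + 1L]] <- list(
              kind = "segment", cluster = cl$id,
              seq = substr(cl$seqs[[1L]], a, a + segBp - 1L),
              vstart = a - 1L, vend = a + segBp - 1L)
          }
          if (planDf$crispr[r]) {
            cl1 <- clusters[[planDf$cluster[r]]]
            repSeq <- randomDna(sample(25:40, 1L))
            nSp <- sample(3:5, 1L)
            nProto <- max(1L, ceiling(nSp / 2))
            spl <- sample(30:40, nSp, replace = TRUE)
            spSeqs <- character(nSp); protoWin <- vector("list", nSp)
            protoIdx <- sample(seq_len(nSp), nProto)
            for (sp in seq_len(nSp)) {
              if (sp %in% protoIdx) {
                a <- sample(seq_len(cl1$length - spl[sp]), 1L)
                spSeqs[sp] <- substr(cl1$seqs[[1L]], a, a + spl[sp] - 1L)
                protoWin[[sp]] <- c(a - 1L, a + spl[sp] - 1L)
              } else {
                spSeqs[sp] <- randomDna(spl[sp])
              }
            }
            arr <- paste0(repSeq,
                          paste0(spSeqs, repSeq, collapse = ""))
            inserts[[length(inserts) + 1L]] <- list(
              kind = "crispr", cluster = cl1$id, seq = arr,
              spacers = spSeqs, protoWin = protoWin, repSeq = repSeq)
          }
        }

        # assemble: distinct ordered cut points in the backbone
        nIns <- length(inserts)
        cuts <- sort(sample(seq(100L, L - 100L), nIns))
        pieces <- character(0)
        prev <- 1L
        insCoord <- integer(0)
        offset <- 0L
        finalStarts <- integer(nIns)
        for (k in seq_len(nIns)) {
          pieces <- c(pieces, substr(backbone, prev, cuts[k]))
          finalStarts[k] <- cuts[k] + offset        # 0-based insert start
          pieces <- c(pieces, inserts[[k]]$seq)
          offset <- offset + nchar(inserts[[k]]$seq)
          prev <- cuts[k] + 1L
        }
        pieces <- c(pieces, substr(backbone, prev, L))
        g1seq <- paste(pieces, collapse = "")

        # record prophage provenance and spacer truth
        for (k in seq_len(nIns)) {
          ins <- inserts[[k]]
          st <- finalStarts[k]
          if (ins$kind == "prophage") {
            prophages[[length(prophages) + 1L]] <- data.frame(
              virus = clusters[[ins$cluster]]$ancestor,
              host_scaffold = g1, start = st, end = st + nchar(ins$seq),
              stringsAsFactors = FALSE)
          } else if (ins$kind == "crispr") {
            repL <- nchar(ins$repSeq)
            spOff <- st + repL
            for (sp in seq_along(ins$spacers)) {
              spacersTruth[[length(spacersTruth) + 1L]] <- data.frame(
                host_scaffold = g1,
                spacer_seq = ins$spacers[sp],
                start = spOff, end = spOff + nchar(ins$spacers[sp]),
                cluster = ins$cluster,
                is_protospacer = !is.null(ins$protoWin[[sp]]),
                proto_start = if (!is.null(ins$protoWin[[sp]]))
                  ins$protoWin[[sp]][1L] else NA_integer_,
                proto_end = if (!is.null(ins$protoWin[[sp]]))
                  ins$protoWin[[sp]][2L] else NA_integer_,
                stringsAsFactors = FALSE)
              spOff <- spOff + nchar(ins$spacers[sp]) + repL
            }
          }
        }

        # member genomes: g1 carries the inserts, the rest are diverged
        # backbone copies (MAG replicates of the same population)
        compl <- round(stats::runif(1, 75, 99), 1)
        cont <- round(stats::runif(1, 0, 8), 1)
        hostSeqs[[g1]] <- g1seq
        hostMeta[[g1]] <- data.frame(
          id = g1, completeness = compl, contamination = cont,
          stringsAsFactors = FALSE)
        hostMember[g1] <- hp
        mems <- g1
        for (m in seq_len(config$members_per_host_population - 1L)) {
          gid <- sprintf("%s_g%d", hp, m + 1L)
          hostSeqs[[gid]] <- mutateSequence(backbone, 0.015)$seq
          hostMeta[[gid]] <- data.frame(
            id = gid, completeness = round(stats::runif(1, 55, 95), 1),
            contamination = round(stats::runif(1, 0, 8), 1),
            stringsAsFactors = FALSE)
          hostMember[gid] <- hp
          mems <- c(mems, gid)
        }
        sc <- vapply(mems, function(g)
          hostMeta[[g]]$completeness - 4 * hostMeta[[g]]$contamination, 0)
        rep_ <- mems[order(-sc, mems)][1L]
        hostRep[hp] <- rep_
        phylumMap[rep_] <- phyla[ph]

        # truth links at the vOTU level, from substitution bookkeeping
        for (r in rows) {
          cl <- clusters[[planDf$cluster[r]]]
          ins <- inserts[[which(vapply(inserts, function(x)
            x$cluster == planDf$cluster[r] &&
              x$kind %in% c("prophage", "segment"), logical(1L)))[1L]]]
          segLen <- ins$vend - ins$vstart
          for (mi in seq_along(cl$members)) {
            lab <- cl$labels[mi]
            nSub <- .subsInWindow(cl$subs[[mi]], ins$vstart, ins$vend)
            idPct <- 100 * (segLen - nSub) / segLen
            if (segLen >= 2500 && idPct >= 70) {
              linksTruth[[length(linksTruth) + 1L]] <- data.frame(
                virus_population = lab, host_population = hp,
                evidence = "homology", stringsAsFactors = FALSE)
            }
          }
          if (planDf$prophage[r]) {
            linksTruth[[length(linksTruth) + 1L]] <- data.frame(
              virus_population = cl$labels[1L], host_population = hp,
              evidence = "prophage", stringsAsFactors = FALSE)
          }
          if (planDf$crispr[r]) {
            wins <- Filter(Negate(is.null),
                           lapply(inserts, function(x)
                             if (x$kind == "crispr" &&
                                 x$cluster == planDf$cluster[r])
                               x$protoWin else NULL))[[1L]]
            wins <- Filter(Negate(is.null), wins)
            for (mi in seq_along(cl$members)) {
              lab <- cl$labels[mi]
              exact <- any(vapply(wins, function(w)
                .subsInWindow(cl$subs[[mi]], w[1L], w[2L]) == 0L,
                logical(1L)))
              if (exact) {
                linksTruth[[length(linksTruth) + 1L]] <- data.frame(
                  virus_population = lab, host_population = hp,
                  evidence = "crispr", stringsAsFactors = FALSE)
              }
            }
          }
        }
      }
    }

    # --- collect viral genomes ------------------------------------------
    for (cl in clusters) {
      for (mi in seq_along(cl$members)) {
        id <- cl$members[mi]
        virSeqs[[id]] <- cl$seqs[[mi]]
        votu[id] <- cl$labels[mi]
        lifestyles[cl$labels[mi]] <- cl$lifestyle
      }
      clusterInfo[[cl$id]] <- cl[c("id", "ancestor", "members", "labels",
                                   "length", "lifestyle")]
    }
    # prophage provenance onto viral metadata
    proDf <- if (length(prophages)) do.call(rbind, prophages) else
      data.frame(virus = character(0), host_scaffold = character(0),
                 start = integer(0), end = integer(0))
    vids <- names(virSeqs)
    vMeta <- data.frame(
      id = vids, kind = "viral",
      lifestyle = unname(lifestyles[votu[vids]]),
      source_scaffold = proDf$host_scaffold[match(vids, proDf$virus)],
      source_start = proDf$start[match(vids, proDf$virus)],
      source_end = proDf$end[match(vids, proDf$virus)],
      stringsAsFactors = FALSE)

    viruses <- Biostrings::DNAStringSet(unlist(virSeqs))
    S4Vectors::mcols(viruses) <- S4Vectors::DataFrame(
      vMeta[match(names(viruses), vMeta$id),
            c("kind", "lifestyle", "source_scaffold", "source_start",
              "source_end")])
    hMetaDf <- do.call(rbind, hostMeta)
    hosts <- Biostrings::DNAStringSet(unlist(hostSeqs))
    S4Vectors::mcols(hosts) <- S4Vectors::DataFrame(
      kind = "prokaryotic",
      completeness = hMetaDf$completeness[match(names(hosts), hMetaDf$id)],
      contamination = hMetaDf$contamination[match(names(hosts), hMetaDf$id)])

    links <- unique(do.call(rbind, linksTruth))
    rownames(links) <- NULL
    spacersDf <- if (length(spacersTruth)) do.call(rbind, spacersTruth) else
      data.frame(host_scaffold = character(0), spacer_seq = character(0),
                 start = integer(0), end = integer(0),
                 cluster = character(0), is_protospacer = logical(0),
                 proto_start = integer(0), proto_end = integer(0))
    truth <- list(
      votu_membership = votu,
      host_membership = hostMember,
      host_representative = hostRep,
      phylum_map = phylumMap,                 # representative genome -> phylum
      links = links,
      lifestyles = lifestyles,                # votu label -> lifestyle
      planted_vhr = config$planted_vhr,
      prophages = proDf,
      clusters = clusterInfo)
    structure(list(
      viruses = viruses, hosts = hosts,
      scaffoldToGenome = data.frame(scaffold = names(hosts),
                                    host_genome = names(hosts),
                                    stringsAsFactors = FALSE),
      taxonomy = data.frame(
        genome = names(hosts),
        phylum = sub("^h_(.+)_r[0-9]+$", "\\1",
                     unname(hostMember[names(hosts)])),
        stringsAsFactors = FALSE),
      spacers = spacersDf,
      truth = truth), class = "simSequences")
  })
}

# Parse phylum / rank / primary-host from a planted viral population label.
.parseVotu <- function(label) {
  m <- regexec("^v_(.+)_r([0-9]+)_([0-9]+)_g[0-9]+$", label)
  g <- regmatches(label, m)[[1L]]
  if (!length(g)) return(NULL)  # background virus
  list(phylum = g[2L], rank = as.integer(g[3L]),
       primary_host = sprintf("h_%s_r%s", g[2L], g[3L]))
}

# Expected (noise-free) host and virus abundance matrices under the
# spatial kernel with decay length lambda (km). Internal to the generator.
.expectedAbundance <- function(config, seqs, samples, lambda, zDriver,
                               homeDist) {
  truth <- seqs$truth
  hpops <- names(truth$host_representative)
  phyla <- config$phyla
  rank <- as.integer(sub("^h_.*_r([0-9]+)$", "\\1", hpops))
  hPhyl <- sub("^h_(.+)_r[0-9]+$", "\\1", hpops)
  gamma <- stats::setNames(seq(-1, 1, length.out = length(phyla)), phyla)
  S <- nrow(samples)
  log10A <- matrix(1 - 0.25 * (rank - 1), length(hpops), S) -
    0.4343 * homeDist[hpops, , drop = FALSE] / lambda +
    0.2 * outer(gamma[hPhyl], zDriver)
  rownames(log10A) <- hpops
  # latitudinal richness truncation: rarer (higher-rank) populations are
  # lost first moving poleward
  present <- matrix(TRUE, length(hpops), S, dimnames = list(hpops, NULL))
  nDrop <- pmin(length(hpops) - 4L,
                pmax(0L, round(config$lat_richness_gradient *
                                 (samples$lat - min(samples$lat)))))
  dropOrder <- order(-rank, hPhyl, hpops)
  for (s in seq_len(S)) {
    if (nDrop[s] > 0L) present[dropOrder[seq_len(nDrop[s])], s] <- FALSE
  }
  hostE <- 10^log10A * present
  # viral populations
  votus <- sort(unique(unname(truth$votu_membership)))
  linkSets <- split(truth$links$host_population, truth$links$virus_population)
  virE <- matrix(0, length(votus), S, dimnames = list(votus, NULL))
  for (v in votus) {
    info <- .parseVotu(v)
    if (is.null(info)) {  # background: modest, unlinked, ubiquitous
      virE[v, ] <- 10^(0.5 - 0.4343 * homeDist[sample(hpops, 1L), ] / lambda)
      next
    }
    linked <- intersect(unique(linkSets[[v]]), hpops)
    if (!length(linked)) linked <- info$primary_host
    vhr <- config$planted_vhr[[info$phylum]]
    pres <- if (info$primary_host %in% hpops)
      hostE[info$primary_host, ] > 0 else rep(TRUE, S)
    virE[v, ] <- vhr * colSums(hostE[linked, , drop = FALSE]) * pres
  }
  list(host = hostE, virus = virE, present = present)
}

# OLS slope of Bray-Curtis similarity on log10 distance (generator-side
# calibration; pairs with zero distance excluded).
.similaritySlope <- function(abund, km) {
  h <- vegan::decostand(t(abund), method = "hellinger")
  bc <- as.matrix(vegan::vegdist(h, method = "bray"))
  lt <- lower.tri(bc)
  d <- km[lt]; sim <- 1 - bc[lt]
  ok <- d > 0 & is.finite(sim)
  unname(stats::coef(stats::lm(sim[ok] ~ log10(d[ok])))[2L])
}

#' Simulate community ecology: abundances, metadata, spatial structure
#'
#' Draws sample coordinates at `n_sites` sites, generates sample metadata
#' from the configured recursive path model (the latitude variable is
#' anchored to the true sample latitudes), and builds host and virus
#' abundance matrices with: lognormal noise, planted per-phylum virus-host
#' abundance ratios (virus abundance = VHR x linked-host abundance x
#' noise), a latitudinal richness gradient, and spatial distance decay via
#' an exponential kernel whose decay length is calibrated numerically
#' against the target slope (the realized noise-free slope is stored in
#' the truth table rather than assumed exact).
#'
#' @param config A [simConfig()].
#' @param seqs Output of [simulateSequences()].
#' @return List of class `"simEcology"`: `virusAbundance` and
#'   `hostAbundance` ([AbundanceMatrix-class], rows keyed by truth
#'   representative genome ids), `metadata` (sample table with
#'   coordinates and path-model variables), `librarySizes`, and `truth`
#'   (expected noise-free matrices, per-phylum mean log10 VHR, realized
#'   distance-decay slope, kernel decay length, planted path
#'   coefficients).
#' @export
simulateEcology <- function(config, seqs) {
  stopifnot(inherits(config, "simConfig"), inherits(seqs, "simSequences"))
  truth <- seqs$truth
  withSeed(deriveSeed(config$seed, "ecology"), {
    nS <- config$n_sites * config$samples_per_site
    siteLat <- stats::runif(config$n_sites, config$lat_range[1L],
                            config$lat_range[2L])
    siteLon <- stats::runif(config$n_sites, config$lon_range[1L],
                            config$lon_range[2L])
    site <- rep(seq_len(config$n_sites), each = config$samples_per_site)
    jit <- config$site_jitter_km / 111
    samples <- data.frame(
      sample = sprintf("S%02d_%02d", site,
                       sequence(rep(config$samples_per_site,
                                    config$n_sites))),
      site = sprintf("site%02d", site),
      lat = siteLat[site] + stats::rnorm(nS, 0, jit),
      lon = siteLon[site] + stats::rnorm(nS, 0, jit),
      stringsAsFactors = FALSE)
    km <- as.matrix(geographicDistance(
      stats::setNames(samples[, c("lat", "lon")], c("lat", "lon"))))

    # metadata from the planted path model, latitude anchored to geography
    spec <- config$path_coefficients
    Sigma <- .impliedSigma(spec)
    vars <- spec$variables
    meta <- matrix(0, nS, length(vars), dimnames = list(NULL, vars))
    for (v in vars) {
      pa <- spec$edges$from[spec$edges$to == v]
      if (!length(pa)) {
        meta[, v] <- if (v == "lat") as.numeric(scale(samples$lat))
                     else stats::rnorm(nS)
      } else {
        b <- spec$edges$coefficient[spec$edges$to == v]
        ev <- 1 - drop(t(b) %*% Sigma[pa, pa, drop = FALSE] %*% b)
        meta[, v] <- meta[, pa, drop = FALSE] %*% b +
          stats::rnorm(nS, sd = sqrt(ev))
      }
    }
    zDriver <- if ("prok_abundance" %in% vars) meta[, "prok_abundance"]
               else rep(0, nS)

    # one home site per host population, fixed across the calibration grid
    hpops <- names(truth$host_representative)
    home <- stats::setNames(sample(config$n_sites, length(hpops),
                                   replace = TRUE), hpops)
    siteKm <- matrix(0, length(hpops), nS, dimnames = list(hpops, NULL))
    firstOfSite <- match(sprintf("site%02d", seq_len(config$n_sites)),
                         samples$site)
    for (p in hpops) siteKm[p, ] <- km[firstOfSite[home[[p]]], ]

    # numeric calibration of the kernel decay length against ddr_slope
    grid <- c(5, 10, 20, 50, 100, 200, 500, 1000, 2000, 5000)
    slopes <- vapply(grid, function(lam) {
      e <- .expectedAbundance(config, seqs, samples, lam, zDriver, siteKm)
      .similaritySlope(e$virus, km)
    }, 0)
    lambda <- grid[which.min(abs(slopes - config$ddr_slope))]
    exp_ <- .expectedAbundance(config, seqs, samples, lambda, zDriver,
                               siteKm)
    # realized slope of the full generative process (with its noise level),
    # estimated on independent internal noise replicates of this layout
    noisyVirus <- function() {
      hN <- exp_$host *
        matrix(exp(stats::rnorm(length(exp_$host), 0, config$noise_sd)),
               nrow(exp_$host))
      vN <- exp_$virus
      for (v in rownames(vN)) {
        info <- .parseVotu(v)
        if (is.null(info)) {
          vN[v, ] <- exp_$virus[v, ] *
            exp(stats::rnorm(ncol(vN), 0, config$noise_sd))
          next
        }
        linked <- intersect(
          unique(truth$links$host_population[
            truth$links$virus_population == v]), rownames(hN))
        if (!length(linked)) linked <- info$primary_host
        vN[v, ] <- config$planted_vhr[[info$phylum]] *
          colSums(hN[linked, , drop = FALSE]) * (exp_$virus[v, ] > 0) *
          exp(stats::rnorm(ncol(vN), 0, config$noise_sd))
      }
      vN
    }
    realizedSlope <- if (config$noise_sd == 0) {
      .similaritySlope(exp_$virus, km)
    } else {
      withSeed(deriveSeed(config$seed, "ddr-replicates"),
               mean(vapply(1:5, function(i)
                 .similaritySlope(noisyVirus(), km), 0)))
    }

    # observed = expected x lognormal noise; virus tracks observed hosts
    sd_ <- config$noise_sd
    hostObs <- exp_$host *
      matrix(exp(stats::rnorm(length(exp_$host), 0, sd_)),
             nrow(exp_$host))
    hostObs[exp_$host == 0] <- 0
    votus <- rownames(exp_$virus)
    linkSets <- split(truth$links$host_population,
                      truth$links$virus_population)
    virObs <- exp_$virus
    for (v in votus) {
      info <- .parseVotu(v)
      if (is.null(info)) {
        virObs[v, ] <- exp_$virus[v, ] * exp(stats::rnorm(nS, 0, sd_))
        next
      }
      linked <- intersect(unique(linkSets[[v]]), hpops)
      if (!length(linked)) linked <- info$primary_host
      vhr <- config$planted_vhr[[info$phylum]]
      pres <- exp_$virus[v, ] > 0
      virObs[v, ] <- vhr * colSums(hostObs[linked, , drop = FALSE]) *
        pres * exp(stats::rnorm(nS, 0, sd_))
    }

    # per-phylum mean log10 VHR on the noise-free matrices (the evidence
    # definition: linked-virus sum over host-phylum sum, co-detected
    # samples only)
    hPhyl <- sub("^h_(.+)_r[0-9]+$", "\\1", hpops)
    linkPhyl <- sub("^h_(.+)_r[0-9]+$", "\\1",
                    truth$links$host_population)
    trueVhr <- stats::setNames(rep(NA_real_, length(config$phyla)),
                               config$phyla)
    for (ph in config$phyla) {
      vir <- unique(truth$links$virus_population[linkPhyl == ph])
      hs <- colSums(exp_$host[hpops[hPhyl == ph], , drop = FALSE])
      vs <- colSums(exp_$virus[intersect(vir, votus), , drop = FALSE])
      ok <- vs > 0 & hs > 0
      if (any(ok)) trueVhr[ph] <- mean(log10(vs[ok] / hs[ok]))
    }

    libs <- stats::setNames(round(stats::runif(nS, 1e6, 3e6)),
                            samples$sample)
    # matrices keyed by representative genome ids
    hostKey <- unname(truth$host_representative[hpops])
    hostMat <- hostObs; rownames(hostMat) <- hostKey
    colnames(hostMat) <- samples$sample
    virMat <- virObs; colnames(virMat) <- samples$sample
    hostExp <- exp_$host; rownames(hostExp) <- hostKey
    colnames(hostExp) <- samples$sample
    virExp <- exp_$virus; colnames(virExp) <- samples$sample

    metadata <- cbind(samples, as.data.frame(meta))
    structure(list(
      virusAbundance = AbundanceMatrix(virMat, libs),
      hostAbundance = AbundanceMatrix(hostMat, libs),
      metadata = metadata,
      librarySizes = libs,
      truth = list(
        expected_virus = virExp,
        expected_host = hostExp,
        true_mean_log10_vhr = trueVhr,
        ddr_slope_realized = realizedSlope,
        lambda_km = lambda,
        path_coefficients = stats::setNames(
          spec$edges$coefficient,
          paste(spec$edges$from, "->", spec$edges$to)))),
      class = "simEcology")
  })
}

#' Simulate a complete dataset
#'
#' Sequences plus ecology under one configuration; the combined truth
#' table covers vOTU membership, links, lifestyles, VHRs, the realized
#' distance-decay slope and the planted path coefficients.
#'
#' @param config A [simConfig()].
#' @return List of class `"simDataset"`: `config`, `sequences`, `ecology`.
#' @export
simulateDataset <- function(config = simConfig()) {
  seqs <- simulateSequences(config)
  eco <- simulateEcology(config, seqs)
  structure(list(config = config, sequences = seqs, ecology = eco),
            class = "simDataset")
}

#' Write a simulated dataset to plain-text files
#'
#' Emits FASTA (viral and host genomes, planted spacers), TSV (abundance
#' matrices, metadata, run-length depth tracks, library sizes, genome
#' metadata, binning map, host taxonomy), a 12-column tabular alignment
#' file for the planted homologies, a JSON truth table, and a manifest
#' listing every file with its md5 checksum. Byte-identical for identical
#' configurations.
#'
#' @param dataset A `"simDataset"` (see [simulateDataset()]).
#' @param outDir Output directory (created if needed).
#' @return Invisibly, the manifest `data.frame` (file, md5).
#' @export
writeDataset <- function(dataset, outDir) {
  stopifnot(inherits(dataset, "simDataset"))
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE)
  if (!ok || file.access(outDir, 2L) != 0L)
    stop("cannot write to directory: ", outDir)
  sq <- dataset$sequences
  eco <- dataset$ecology
  wTsv <- function(x, f) utils::write.table(
    x, file.path(outDir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(sq$viruses,
                              file.path(outDir, "viral_genomes.fasta"))
  Biostrings::writeXStringSet(sq$hosts,
                              file.path(outDir, "host_genomes.fasta"))
  if (nrow(sq$spacers)) {
    sp <- Biostrings::DNAStringSet(sq$spacers$spacer_seq)
    names(sp) <- sprintf("%s|spacer%03d", sq$spacers$host_scaffold,
                         seq_len(nrow(sq$spacers)))
    Biostrings::writeXStringSet(sp, file.path(outDir, "spacers.fasta"))
  }
  vm <- S4Vectors::mcols(sq$viruses)
  genomeMeta <- rbind(
    data.frame(id = names(sq$viruses), kind = "viral",
               completeness = NA_real_, contamination = NA_real_,
               lifestyle = vm$lifestyle,
               source_scaffold = vm$source_scaffold,
               source_start = vm$source_start,
               source_end = vm$source_end, stringsAsFactors = FALSE),
    data.frame(id = names(sq$hosts), kind = "prokaryotic",
               completeness = S4Vectors::mcols(sq$hosts)$completeness,
               contamination = S4Vectors::mcols(sq$hosts)$contamination,
               lifestyle = NA_character_, source_scaffold = NA_character_,
               source_start = NA_integer_, source_end = NA_integer_,
               stringsAsFactors = FALSE))
  wTsv(genomeMeta, "genome_metadata.tsv")
  wTsv(sq$scaffoldToGenome, "binning.tsv")
  wTsv(sq$taxonomy, "host_taxonomy.tsv")
  writeAbund <- function(am, f) {
    m <- abundance(am)
    wTsv(data.frame(entity = rownames(m), m, check.names = FALSE), f)
  }
  writeAbund(eco$virusAbundance, "abundance_viral.tsv")
  writeAbund(eco$hostAbundance, "abundance_host.tsv")
  wTsv(data.frame(sample = names(eco$librarySizes),
                  reads = unname(eco$librarySizes)), "library_sizes.tsv")
  wTsv(eco$metadata, "metadata.tsv")
  # depth tracks: one constant run per detected (entity, sample); depth is
  # raw coverage (abundance un-normalized by library size)
  lens <- c(stats::setNames(Biostrings::width(sq$viruses),
                            names(sq$viruses)),
            stats::setNames(Biostrings::width(sq$hosts), names(sq$hosts)))
  meanLib <- mean(eco$librarySizes)
  depth <- list()
  for (am in list(eco$virusAbundance, eco$hostAbundance)) {
    m <- abundance(am)
    idx <- which(m > 0, arr.ind = TRUE)
    if (nrow(idx)) {
      ent <- rownames(m)[idx[, 1L]]
      smp <- colnames(m)[idx[, 2L]]
      depth[[length(depth) + 1L]] <- data.frame(
        entity = ent, sample = smp, length = unname(lens[ent]),
        depth = m[idx] * unname(eco$librarySizes[smp]) / meanLib,
        stringsAsFactors = FALSE)
    }
  }
  depth <- do.call(rbind, depth)
  depth <- depth[order(depth$entity, depth$sample), ]
  wTsv(depth, "depth_runs.tsv")
  # planted homology hits in tabular alignment format (generator
  # bookkeeping, usable in place of an external aligner's output)
  hits <- .plantedHomologyHits(dataset)
  wTsv(hits, "homology_hits.tsv")
  truth <- dataset$sequences$truth
  truthOut <- list(
    votu_membership = as.list(truth$votu_membership),
    host_membership = as.list(truth$host_membership),
    host_representative = as.list(truth$host_representative),
    phylum_map = as.list(truth$phylum_map),
    links = truth$links,
    lifestyles = as.list(truth$lifestyles),
    planted_vhr = as.list(truth$planted_vhr),
    prophages = truth$prophages,
    true_mean_log10_vhr = as.list(eco$truth$true_mean_log10_vhr),
    ddr_slope_realized = eco$truth$ddr_slope_realized,
    lambda_km = eco$truth$lambda_km,
    path_coefficients = as.list(eco$truth$path_coefficients))
  jsonlite::write_json(truthOut, file.path(outDir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  files <- sort(setdiff(list.files(outDir), "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outDir, files))),
    stringsAsFactors = FALSE)
  wTsv(manifest, "manifest.tsv")
  invisible(manifest)
}

# Tabular hits for every planted shared segment / prophage, derived from
# generator bookkeeping (exact coordinates and identities).
.plantedHomologyHits <- function(dataset) {
  sq <- dataset$sequences
  truth <- sq$truth
  out <- list()
  vlen <- stats::setNames(Biostrings::width(sq$viruses), names(sq$viruses))
  hlen <- stats::setNames(Biostrings::width(sq$hosts), names(sq$hosts))
  hseq <- as.character(sq$hosts)
  vseq <- as.character(sq$viruses)
  # recompute each planted insert's exact hit per virus member by direct
  # comparison of the stored sequences (single forward diagonal)
  for (cl in truth$clusters) {
    for (hp in unique(truth$links$host_population[
      truth$links$virus_population %in% cl$labels])) {
      g1 <- paste0(hp, "_g1")
      h <- findNucleotideHits(vseq[[cl$ancestor]], hseq[[g1]],
                              minLen = 1000L)
      h <- h[h$strand == "+", , drop = FALSE]
      if (!nrow(h)) next
      h <- h[which.max(h$length), , drop = FALSE]
      for (mi in seq_along(cl$members)) {
        gid <- cl$members[mi]
        sub <- substr(vseq[[gid]], h$qstart, h$qend)
        ref <- substr(hseq[[g1]], h$sstart, h$send)
        matches <- hammingMatches(sub, ref)
        ka <- kaStats(matches, h$length - matches, vlen[[gid]], hlen[[g1]])
        out[[length(out) + 1L]] <- data.frame(
          qseqid = gid, sseqid = g1,
          pident = 100 * matches / h$length, length = h$length,
          mismatch = h$length - matches, gapopen = 0L,
          qstart = h$qstart, qend = h$qend,
          sstart = h$sstart, send = h$send,
          evalue = ka$evalue, bitscore = ka$bits,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(qseqid = character(0), sseqid = character(0),
                      pident = numeric(0), length = integer(0),
                      mismatch = integer(0), gapopen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      evalue = numeric(0), bitscore = numeric(0))
  rownames(res) <- NULL
  res
}

#' Read a written dataset back
#'
#' Round-trips the plain-text files emitted by [writeDataset()].
#'
#' @param dir Dataset directory.
#' @return List with `viruses`, `hosts` ([Biostrings::DNAStringSet]),
#'   `genomeMeta`, `binning`, `taxonomy`, `virusAbundance`,
#'   `hostAbundance`, `metadata`, `depthRuns`, `homologyHits`,
#'   `librarySizes`, `truth`.
#' @export
readDataset <- function(dir) {
  rTsv <- function(f, ...) utils::read.delim(file.path(dir, f),
                                             stringsAsFactors = FALSE, ...)
  libs <- rTsv("library_sizes.tsv")
  librarySizes <- stats::setNames(libs$reads, libs$sample)
  rAbund <- function(f) {
    x <- rTsv(f, check.names = FALSE)
    m <- as.matrix(x[, -1L, drop = FALSE])
    rownames(m) <- x$entity
    AbundanceMatrix(m, librarySizes)
  }
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  for (f in c("votu_membership", "host_membership", "host_representative",
              "phylum_map", "lifestyles", "planted_vhr",
              "true_mean_log10_vhr", "path_coefficients"))
    truth[[f]] <- unlist(truth[[f]])
  list(
    viruses = Biostrings::readDNAStringSet(
      file.path(dir, "viral_genomes.fasta")),
    hosts = Biostrings::readDNAStringSet(
      file.path(dir, "host_genomes.fasta")),
    genomeMeta = rTsv("genome_metadata.tsv"),
    binning = rTsv("binning.tsv"),
    taxonomy = rTsv("host_taxonomy.tsv"),
    virusAbundance = rAbund("abundance_viral.tsv"),
    hostAbundance = rAbund("abundance_host.tsv"),
    metadata = rTsv("metadata.tsv"),
    depthRuns = rTsv("depth_runs.tsv"),
    homologyHits = rTsv("homology_hits.tsv"),
    librarySizes = librarySizes,
    truth = truth)
}
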