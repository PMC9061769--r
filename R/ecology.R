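# Lineage-level virus-host dynamics: virus-host abundance ratios (VHRs),
# abundance correlations, host range / viral range, and lifestyle trends.

# Virus populations linked to any host population of each phylum.
.phylumVirusSets <- function(links, phylumMap) {
  ph <- unname(phylumMap[links$host_population])
  split(links$virus_population, ph)
}

#' Lineage-specific virus-host abundance ratios
#'
#' Per sample and host phylum, VHR = summed abundance of virus populations
#' linked to the phylum divided by summed abundance of the phylum's host
#' populations. Samples where either sum is zero are excluded. Reported as
#' per-sample ratios plus the mean of their log10 values
#' (`aggregation = "mean-of-ratios"`, the default) or the log10 of the
#' ratio of per-sample means (`"ratio-of-means"`).
#'
#' Viruses linked to several phyla contribute their full abundance to each
#' (matching the "viruses infecting the same host lineage" reading);
#' `split = TRUE` divides each virus's abundance equally among its linked
#' phyla instead.
#'
#' @param virusAbund,hostAbund [AbundanceMatrix-class] objects at the
#'   population level.
#' @param links Population-level links (virus_population, host_population).
#' @param phylumMap Named vector, host population -> phylum.
#' @param aggregation `"mean-of-ratios"` or `"ratio-of-means"`.
#' @param split Split multi-phylum virus abundance equally among phyla.
#' @return `data.frame` with columns phylum, n_samples, mean_log10_vhr, and
#'   attribute `"vhr"`: a named list of per-sample VHR vectors.
#' @export
lineageVhr <- function(virusAbund, hostAbund, links, phylumMap,
                       aggregation = c("mean-of-ratios", "ratio-of-means"),
                       split = FALSE) {
  aggregation <- match.arg(aggregation)
  va <- abundance(virusAbund)
  ha <- abundance(hostAbund)
  samples <- intersect(colnames(va), colnames(ha))
  vsets <- .phylumVirusSets(links, phylumMap)
  vPhylumCount <- table(unique(data.frame(
    v = links$virus_population,
    p = unname(phylumMap[links$host_population])))$v)
  phyla <- sort(unique(unname(phylumMap)))
  vhrs <- list()
  rows <- list()
  for (p in phyla) {
    hosts <- names(phylumMap)[phylumMap == p]
    hosts <- intersect(hosts, rownames(ha))
    vir <- unique(vsets[[p]])
    vir <- intersect(vir, rownames(va))
    if (!length(vir)) {
      warning("phylum ", p, " has no linked viruses; omitted")
      next
    }
    w <- if (split) 1 / as.numeric(vPhylumCount[vir]) else rep(1, length(vir))
    vs <- colSums(va[vir, samples, drop = FALSE] * w)
    hs <- colSums(ha[hosts, samples, drop = FALSE])
    ok <- vs > 0 & hs > 0
    ratio <- vs[ok] / hs[ok]
    vhrs[[p]] <- ratio
    ml <- switch(aggregation,
                 "mean-of-ratios" = mean(log10(ratio)),
                 "ratio-of-means" = log10(mean(vs[ok]) / mean(hs[ok])))
    rows[[p]] <- data.frame(phylum = p, n_samples = sum(ok),
                            mean_log10_vhr = ml, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "vhr") <- vhrs
  res
}

#' Lineage-level virus-host abundance correlation
#'
#' Pearson correlation (with two-tailed p) between the summed abundance of
#' a phylum's host populations and the summed abundance of viruses linked
#' to that phylum, across samples where both are detected (> 0). Phyla with
#' fewer than three co-detected samples, or a zero-variance vector, are
#' flagged undefined (NA).
#'
#' @inheritParams lineageVhr
#' @return `data.frame` with columns phylum, n_samples, r, p.
#' @export
lineageAbundanceCorrelation <- function(virusAbund, hostAbund, links,
                                        phylumMap) {
  va <- abundance(virusAbund)
  ha <- abundance(hostAbund)
  samples <- intersect(colnames(va), colnames(ha))
  vsets <- .phylumVirusSets(links, phylumMap)
  phyla <- sort(unique(unname(phylumMap)))
  rows <- lapply(phyla, function(p) {
    hosts <- intersect(names(phylumMap)[phylumMap == p], rownames(ha))
    vir <- intersect(unique(vsets[[p]]), rownames(va))
    if (!length(vir))
      return(data.frame(phylum = p, n_samples = 0L, r = NA_real_,
                        p = NA_real_))
    vs <- colSums(va[vir, samples, drop = FALSE])
    hs <- colSums(ha[hosts, samples, drop = FALSE])
    ok <- vs > 0 & hs > 0
    if (sum(ok) < 3L || stats::sd(vs[ok]) == 0 || stats::sd(hs[ok]) == 0)
      return(data.frame(phylum = p, n_samples = sum(ok), r = NA_real_,
                        p = NA_real_))
    ct <- stats::cor.test(hs[ok], vs[ok], method = "pearson")
    data.frame(phylum = p, n_samples = sum(ok),
               r = unname(ct$estimate), p = ct$p.value)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Lineage-level host range and viral range
#'
#' Host range of a virus population = number of distinct host populations
#' it links to; viral range of a host population = number of distinct virus
#' populations linking to it. Lineage values are the means over viruses
#' linked to (respectively hosts belonging to) each phylum.
#'
#' @param links Population-level links.
#' @param phylumMap Named vector, host population -> phylum.
#' @return `data.frame` with columns phylum, n_host_populations,
#'   n_virus_populations, host_range_mean, viral_range_mean. Zero-row for
#'   an empty link set.
#' @export
hostViralRange <- function(links, phylumMap) {
  if (!nrow(links))
    return(data.frame(phylum = character(0), n_host_populations = integer(0),
                      n_virus_populations = integer(0),
                      host_range_mean = numeric(0),
                      viral_range_mean = numeric(0)))
  hostRange <- vapply(split(links$host_population, links$virus_population),
                      function(h) length(unique(h)), 0L)
  viralRange <- vapply(split(links$virus_population, links$host_population),
                       function(v) length(unique(v)), 0L)
  ph <- unname(phylumMap[links$host_population])
  phyla <- sort(unique(ph))
  rows <- lapply(phyla, function(p) {
    hp <- unique(links$host_population[ph == p])
    vp <- unique(links$virus_population[ph == p])
    data.frame(phylum = p,
               n_host_populations = length(hp),
               n_virus_populations = length(vp),
               host_range_mean = mean(hostRange[vp]),
               viral_range_mean = mean(viralRange[hp]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Lifestyle (virulent/temperate) relative-abundance trends
#'
#' Per sample, the summed relative abundance of virulent and of temperate
#' virus populations (class sum divided by total viral abundance; unknowns
#' contribute to the denominator but to neither class), regressed by least
#' squares on total prokaryotic abundance with two-tailed p-values.
#'
#' @param virusAbund [AbundanceMatrix-class] of virus populations.
#' @param lifestyles Named character vector, virus population ->
#'   "virulent"/"temperate"/"unknown".
#' @param prokaryoteTotals Named numeric vector of total prokaryotic
#'   abundance per sample.
#' @return List with `per_sample` (`data.frame`: sample, prok_total,
#'   virulent, temperate) and `trend` (`data.frame`: class, slope, p,
#'   adj_r2).
#' @export
lifestyleRatioTrend <- function(virusAbund, lifestyles, prokaryoteTotals) {
  va <- abundance(virusAbund)
  ls <- lifestyles[rownames(va)]
  if (all(is.na(ls) | ls == "unknown"))
    stop("all lifestyle labels unknown")
  total <- colSums(va)
  virl <- colSums(va[which(ls == "virulent"), , drop = FALSE])
  temp <- colSums(va[which(ls == "temperate"), , drop = FALSE])
  samples <- intersect(colnames(va), names(prokaryoteTotals))
  per <- data.frame(sample = samples,
                    prok_total = unname(prokaryoteTotals[samples]),
                    virulent = ifelse(total[samples] > 0,
                                      virl[samples] / total[samples], NA),
                    temperate = ifelse(total[samples] > 0,
                                       temp[samples] / total[samples], NA),
                    stringsAsFactors = FALSE)
  fitOne <- function(y) {
    ok <- is.finite(y) & is.finite(per$prok_total)
    if (sum(ok) < 2L || stats::sd(per$prok_total[ok]) == 0)
      return(c(slope = NA_real_, p = NA_real_, adj_r2 = NA_real_))
    if (stats::sd(y[ok]) == 0)
      return(c(slope = 0, p = NA_real_, adj_r2 = NA_real_))
    f <- stats::lm(y[ok] ~ per$prok_total[ok])
    s <- summary(f)
    c(slope = unname(stats::coef(f)[2L]),
      p = if (f$df.residual >= 1L) s$coefficients[2L, 4L] else NA_real_,
      adj_r2 = s$adj.r.squared)
  }
  tr <- rbind(virulent = fitOne(per$virulent),
              temperate = fitOne(per$temperate))
  trend <- data.frame(class = rownames(tr), tr, row.names = NULL)
  list(per_sample = per, trend = trend)
}

#' Per-lineage virulent:temperate abundance ratios and group comparison
#'
#' For each host phylum, the ratio of summed virulent to summed temperate
#' abundance of its linked viruses, per sample; two phyla can be compared
#' with an unpaired Wilcoxon rank-sum test.
#'
#' @inheritParams lineageVhr
#' @param lifestyles Named vector, virus population -> lifestyle.
#' @param compare Optional character(2) of phylum names to compare.
#' @return List with `ratios` (named list of per-sample ratio vectors) and,
#'   when `compare` is given, `wilcox` (the [stats::wilcox.test()] result).
#' @export
virulentTemperateRatio <- function(virusAbund, lifestyles, links, phylumMap,
                                   compare = NULL) {
  va <- abundance(virusAbund)
  vsets <- .phylumVirusSets(links, phylumMap)
  ratios <- lapply(vsets, function(vir) {
    vir <- intersect(unique(vir), rownames(va))
    ls <- lifestyles[vir]
    v <- colSums(va[vir[which(ls == "virulent")], , drop = FALSE])
    t <- colSums(va[vir[which(ls == "temperate")], , drop = FALSE])
    ok <- v > 0 & t > 0
    (v / t)[ok]
  })
  out <- list(ratios = ratios)
  if (!is.null(compare)) {
    stopifnot(length(compare) == 2L, all(compare %in% names(ratios)))
    out$wilcox <- stats::wilcox.test(ratios[[compare[1L]]],
                                     ratios[[compare[2L]]], paired = FALSE)
  }
  out
}

#' Polynomial fit of viral abundance against prokaryotic abundance
#'
#' Least-squares polynomial regression (degree 2 by default, the
#' lowest-order curve able to express a peaked abundance-abundance
#' relationship) of total viral abundance on total prokaryotic abundance
#' across samples. Model-degree selection is deliberately not automated.
#'
#' @param prokTotal,viralTotal Named numeric per-sample totals.
#' @param degree Polynomial degree (>= 1).
#' @return List: `coefficients`, `adj_r2`, `p` (overall F-test),
#'   `fitted` (named by sample), `degree`.
#' @export
abundanceRelationshipFit <- function(prokTotal, viralTotal, degree = 2L) {
  samples <- intersect(names(prokTotal), names(viralTotal))
  if (length(samples) < degree + 2L)
    stop("need at least degree + 2 samples")
  x <- prokTotal[samples]; y <- viralTotal[samples]
  f <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  s <- summary(f)
  fstat <- s$fstatistic
  list(coefficients = unname(stats::coef(f)),
       adj_r2 = s$adj.r.squared,
       p = unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                            lower.tail = FALSE)),
       fitted = stats::setNames(stats::fitted(f), samples),
       degree = degree)
}
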