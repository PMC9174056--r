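# Per-neuron and per-group statistics: counts and sizes per vesicle class
# "per neuronal cross-section", colocalization fractions, mean +/- s.e.m.
# and the two-tailed unpaired Student's t-test.

#' Per-neuron metrics from classified vesicle calls
#'
#' @param calls classified punctum table ([classifyField()] output with
#'   `neuron_id`), possibly spanning many neurons.
#' @param neuronIds neuron ids to report (defaults to those present);
#'   pass the full ground-truth id set so neurons with zero puncta appear
#'   as zero rows.
#' @return data.frame with one row per neuron: counts per class, mean area
#'   per class (um^2, `NA` where a class is absent), `n_abeta`/`n_pla`
#'   punctum counts, and per-class fractions of the marker-positive puncta.
#' @export
perNeuronMetrics <- function(calls, neuronIds = NULL) {
  if (is.null(neuronIds)) {
    neuronIds <- sort(unique(calls$neuron_id[!is.na(calls$neuron_id)]))
  }
  classes <- .vesicleClasses
  rows <- lapply(neuronIds, function(id) {
    cc <- calls[!is.na(calls$neuron_id) & calls$neuron_id == id, , drop = FALSE]
    row <- list(neuron_id = id)
    for (k in classes) {
      sel <- cc$klass == k
      row[[paste0("n_", k)]] <- sum(sel)
      row[[paste0("area_", k)]] <- if (any(sel)) mean(cc$area_um2[sel]) else NA_real_
    }
    row$n_unclassified <- sum(cc$klass == "unclassified")
    for (mk in c("abeta", "pla")) {
      pos <- cc[[paste0(mk, "_pos")]]
      if (is.null(pos)) pos <- rep(FALSE, nrow(cc))
      row[[paste0("n_", mk)]] <- sum(pos)
      for (k in classes) {
        row[[paste0("frac_", mk, "_", k)]] <-
          if (sum(pos) > 0) sum(pos & cc$klass == k) / sum(pos) else NA_real_
      }
    }
    as.data.frame(row)
  })
  do.call(rbind, rows)
}

#' Group summary: mean, s.e.m. and n
#'
#' s.e.m. uses the sample standard deviation (n - 1 denominator) divided by
#' `sqrt(n)`, the dispersion statistic used throughout.
#'
#' @param values numeric vector (NAs dropped).
#' @return list with `mean`, `sem`, `n`.
#' @export
groupSummary <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("groupSummary needs at least one value")
  list(mean = mean(values),
       sem = if (n > 1) stats::sd(values) / sqrt(n) else 0,
       n = n)
}

#' Two-tailed unpaired Student's t-test
#'
#' Pooled-variance Student's t with `nA + nB - 2` degrees of freedom and a
#' two-tailed p-value. Degenerate zero-variance inputs follow the
#' documented conventions: equal means give `t = 0, p = 1`; unequal means
#' give `p = 0` flagged degenerate.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @return list with group means, sems, ns, `t`, `df`, `p`, `degenerate`.
#' @export
unpairedTTest <- function(groupA, groupB) {
  groupA <- groupA[!is.na(groupA)]; groupB <- groupB[!is.na(groupB)]
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2 || nB < 2) stop("both groups need at least two values")
  df <- nA + nB - 2
  sp2 <- ((nA - 1) * stats::var(groupA) + (nB - 1) * stats::var(groupB)) / df
  delta <- mean(groupA) - mean(groupB)
  degenerate <- FALSE
  if (sp2 <= 0) {
    if (delta == 0) { t <- 0; p <- 1 } else { t <- Inf * sign(delta); p <- 0
      degenerate <- TRUE }
  } else {
    t <- delta / sqrt(sp2 * (1 / nA + 1 / nB))
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(meanA = mean(groupA), semA = groupSummary(groupA)$sem, nA = nA,
       meanB = mean(groupB), semB = groupSummary(groupB)$sem, nB = nB,
       t = t, df = df, p = p, degenerate = degenerate)
}

#' Colocalization fractions by vesicle class
#'
#' Among marker-positive puncta (amyloid or PLA), the fraction belonging to
#' each class - pooled over all puncta, and as the mean of per-neuron
#' fractions with its s.e.m. (the per-neuron unit of analysis used for
#' reporting).
#'
#' @param calls classified punctum table with `neuron_id` and
#'   `abeta_pos`/`pla_pos`.
#' @param marker `"abeta"` or `"pla"`.
#' @return list with `pooled` (named fractions), `perNeuron` (mean, sem, n
#'   per class over neurons that have at least one marker-positive
#'   punctum), and `nPositive`.
#' @export
colocalizationFractions <- function(calls, marker = c("abeta", "pla")) {
  marker <- match.arg(marker)
  pos <- calls[[paste0(marker, "_pos")]]
  if (is.null(pos)) stop("calls carry no ", marker, " positivity column")
  nPos <- sum(pos, na.rm = TRUE)
  if (nPos == 0) {
    return(list(pooled = NULL, perNeuron = NULL, nPositive = 0,
                flag = "no marker-positive puncta"))
  }
  classes <- .vesicleClasses
  pooled <- vapply(classes, function(k) {
    sum(pos & calls$klass == k, na.rm = TRUE) / nPos
  }, 0)
  met <- perNeuronMetrics(calls)
  perNeuron <- lapply(classes, function(k) {
    v <- met[[paste0("frac_", marker, "_", k)]]
    v <- v[!is.na(v)]
    if (!length(v)) return(list(mean = NA_real_, sem = NA_real_, n = 0))
    groupSummary(v)
  })
  names(perNeuron) <- classes
  list(pooled = pooled, perNeuron = perNeuron, nPositive = nPos)
}
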