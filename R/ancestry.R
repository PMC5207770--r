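# Local-ancestry queries: global ancestry from tract lengths, diploid
# ancestry dosage at arbitrary coordinates, and interpolation of dosage at
# CpG sites from the dosages at flanking SNPs (ancestry LD is much stronger
# than genotypic LD, so interpolation in genetic distance is accurate except
# within one inter-SNP gap of a tract switch).

# check per-haplotype tiling: starts at 0, ends at L, contiguous
validate_tracts <- function(tracts) {
  L <- attr(tracts, "genetic_length")
  key <- paste(tracts$indiv, tracts$hap, sep = "\r")
  for (tr in split(tracts, key)) {
    ok <- isTRUE(all.equal(tr$start[1], 0)) &&
      isTRUE(all.equal(tr$end[nrow(tr)], L)) &&
      (nrow(tr) == 1L || all(abs(tr$start[-1L] - tr$end[-nrow(tr)]) < 1e-9))
    if (!ok) {
      abort_admix("local-ancestry tracts do not tile the interval",
                  "admixmeth_invariant")
    }
  }
  invisible(TRUE)
}

#' Global ancestry from local-ancestry tracts
#'
#' Length-weighted mean ancestry dosage over both haplotypes, divided by 2;
#' the genome-wide average of local ancestry, which is the usual tract-based
#' estimate of global ancestry proportions.
#'
#' @param tracts Cohort tract table ([simulate_cohort_tracts()] or
#'   [read_tracts_bed()]).
#' @param check Validate the tiling invariant first (raises an error on
#'   gaps or misordered tracts).
#' @return Individuals x K matrix of proportions; rows sum to 1.
#' @export
global_from_local <- function(tracts, check = TRUE) {
  if (check) validate_tracts(tracts)
  labels <- attr(tracts, "labels")
  L <- attr(tracts, "genetic_length")
  len <- tracts$end - tracts$start
  tot <- rowsum(len, group = paste(tracts$indiv, tracts$ancestry,
                                   sep = "\r"), reorder = FALSE)
  ids <- unique(tracts$indiv)
  out <- matrix(0, length(ids), length(labels),
                dimnames = list(ids, labels))
  parts <- do.call(rbind, strsplit(rownames(tot), "\r", fixed = TRUE))
  out[cbind(match(parts[, 1L], ids), match(parts[, 2L], labels))] <-
    tot[, 1L]
  out / (2 * L)
}

#' Diploid local-ancestry dosage at a position
#'
#' @param tracts Cohort tract table.
#' @param pos_gen Genetic position (Morgans), scalar.
#' @return Individuals x K matrix with entries in {0, 1, 2}; rows sum to 2.
#' @export
local_dosage_at <- function(tracts, pos_gen) {
  labels <- attr(tracts, "labels")
  L <- attr(tracts, "genetic_length")
  if (pos_gen < 0 || pos_gen >= L) {
    abort_admix("query position outside simulated interval",
                "admixmeth_coordinate")
  }
  cover <- tracts$start <= pos_gen & tracts$end > pos_gen
  hit <- tracts[cover, , drop = FALSE]
  ids <- unique(tracts$indiv)
  out <- matrix(0, length(ids), length(labels),
                dimnames = list(ids, labels))
  for (r in seq_len(nrow(hit))) {
    i <- match(hit$indiv[r], ids)
    k <- match(hit$ancestry[r], labels)
    out[i, k] <- out[i, k] + 1
  }
  if (any(rowSums(out) != 2)) {
    abort_admix("local-ancestry tracts do not tile the interval",
                "admixmeth_invariant")
  }
  out
}

#' Interpolate ancestry dosage at query positions
#'
#' Given per-SNP diploid ancestry dosages for one individual, returns the
#' dosage at arbitrary query coordinates: the shared value where the
#' flanking SNPs agree, a linear interpolation in genetic distance where
#' they disagree, and the nearest SNP's dosage outside the SNP range. A
#' query exactly at a SNP returns that SNP's dosage (ties toward the left
#' SNP).
#'
#' @param dosages SNPs x K matrix of ancestry dosages (rows sum to 2).
#' @param pos Genetic positions of the SNPs, strictly increasing.
#' @param query Query positions (vector).
#' @return `length(query)` x K matrix; rows sum to 2, entries in \[0, 2\].
#' @export
interpolate_at <- function(dosages, pos, query) {
  stopifnot(is.matrix(dosages), length(pos) == nrow(dosages))
  if (nrow(dosages) < 1L) {
    abort_admix("at least one SNP required", "admixmeth_invalid")
  }
  if (is.unsorted(pos, strictly = TRUE)) {
    abort_admix("SNP positions must be strictly increasing",
                "admixmeth_invalid")
  }
  out <- matrix(NA_real_, length(query), ncol(dosages),
                dimnames = list(NULL, colnames(dosages)))
  left <- findInterval(query, pos)
  for (i in seq_along(query)) {
    l <- left[i]
    if (l == 0L) {                       # before the first SNP
      out[i, ] <- dosages[1L, ]
    } else if (l == length(pos)) {       # at/after the last SNP
      out[i, ] <- dosages[length(pos), ]
    } else if (query[i] == pos[l]) {     # exactly at a SNP
      out[i, ] <- dosages[l, ]
    } else {
      w <- (pos[l + 1L] - query[i]) / (pos[l + 1L] - pos[l])
      out[i, ] <- w * dosages[l, ] + (1 - w) * dosages[l + 1L, ]
    }
  }
  out
}

#' True SNP ancestry dosages for a cohort
#'
#' Convenience truth extractor: diploid ancestry dosage of every individual
#' at every SNP, taken directly from the simulated tracts.
#'
#' @param tracts Cohort tract table.
#' @param positions Genetic positions (e.g. `panel$snps$pos_gen`).
#' @return 3-d array (individuals x K x positions) of dosages in {0,1,2}.
#' @keywords internal
cohort_dosage_array <- function(tracts, positions) {
  labels <- attr(tracts, "labels")
  ids <- unique(tracts$indiv)
  arr <- array(0, dim = c(length(ids), length(labels), length(positions)),
               dimnames = list(ids, labels, NULL))
  key <- paste(tracts$indiv, tracts$hap, sep = "\r")
  for (tr in split(tracts, key)) {
    i <- match(tr$indiv[1L], ids)
    idx <- findInterval(positions, tr$start)
    k <- match(tr$ancestry[idx], labels)
    for (p in seq_along(positions)) {
      arr[i, k[p], p] <- arr[i, k[p], p] + 1
    }
  }
  arr
}
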