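#' Duplex-design parameters
#'
#' Policy knobs for combining two SSR markers into one duplex PCR:
#' `min_gap_bp` is the minimum separation between the two loci's allele-size
#' ranges (default 10 bp, wide enough to score non-allelic bands
#' unambiguously on a gel); `min_cm` the minimum map distance between loci
#' on the same linkage group (default 10 cM, avoiding tight linkage in
#' parentage work); `prefer_longer_motifs` gates pairs on both members
#' having repeat units of three or more bases (less PCR slippage);
#' `objective` selects what the assembler maximizes.
#'
#' @param min_gap_bp minimum band-range gap in base pairs (>= 0).
#' @param min_cm minimum within-linkage-group distance in centiMorgans.
#' @param prefer_longer_motifs require tri- or longer repeat units.
#' @param objective `"max_total_pic"` (default: total PIC over paired
#'   markers) or `"max_pairs"` (as many duplexes as possible, PIC as
#'   tie-break).
#' @return list of class `design_params`.
#' @export
design_params <- function(min_gap_bp = 10, min_cm = 10,
                          prefer_longer_motifs = FALSE,
                          objective = c("max_total_pic", "max_pairs")) {
  stopifnot(min_gap_bp >= 0, min_cm >= 0)
  structure(list(min_gap_bp = min_gap_bp, min_cm = min_cm,
                 prefer_longer_motifs = prefer_longer_motifs,
                 objective = match.arg(objective)),
            class = "design_params")
}

marker_row <- function(markers, id) {
  if (is.data.frame(markers) && nrow(markers) == 1 && missing(id)) return(markers)
  i <- match(id, markers$id)
  if (is.na(i)) stop("unknown marker id: ", id)
  markers[i, , drop = FALSE]
}

#' Gap between two markers' allele-size ranges
#'
#' The size-range separation of the pair: the lower bound of the
#' higher-ranged marker minus the upper bound of the lower-ranged one.
#' Negative or zero when the ranges overlap or touch. Symmetric in its
#' arguments.
#'
#' @param a,b single marker rows (data.frames carrying `size_min_bp`,
#'   `size_max_bp`).
#' @return Gap in base pairs (may be negative).
#' @export
range_gap <- function(a, b) {
  need <- c("size_min_bp", "size_max_bp")
  if (anyNA(unlist(a[need])) || anyNA(unlist(b[need]))) {
    stop("range_gap needs size_min_bp/size_max_bp on both markers")
  }
  if (a$size_min_bp >= b$size_min_bp) a$size_min_bp - b$size_max_bp
  else b$size_min_bp - a$size_max_bp
}

#' Observed minimum band separation between two loci
#'
#' The smallest absolute size difference over all pairs of bands actually
#' observed at the two loci in a genotype panel — the separation a scorer
#' sees on the gel, which can exceed the range-based gap when the observed
#' alleles are sparse within their ranges.
#'
#' @param panel a [genotype_panel()] with numeric (bp) allele labels.
#' @param a,b marker ids.
#' @return Minimum separation in base pairs.
#' @export
observed_min_separation <- function(panel, a, b) {
  bands <- function(m) {
    if (!m %in% colnames(panel$allele1)) stop("unknown marker id: ", m)
    v <- suppressWarnings(as.numeric(c(panel$allele1[, m], panel$allele2[, m])))
    v <- unique(v[!is.na(v)])
    if (!length(v)) stop("no observed bands at locus ", m)
    v
  }
  min(abs(outer(bands(a), bands(b), "-")))
}

#' Evaluate the duplex-compatibility criteria for a marker pair
#'
#' The six pairing criteria, as computable checks:
#' \enumerate{
#'   \item non-overlapping allele-size ranges, separated by at least
#'     `min_gap_bp` (gate);
#'   \item empirical duplex amplification quality — a metadata flag
#'     (`quality_ok` column, default pass; gate);
#'   \item high polymorphism — PIC is recorded and used as the assembly
#'     weight, never as a gate;
#'   \item two clean bands per genotype under disomic inheritance — a
#'     metadata flag (`disomic_ok` column, default pass; gate);
#'   \item map distance: different linkage groups always pass; loci on one
#'     linkage group need `>= min_cm` centiMorgans between them (gate);
#'   \item repeat-motif preference (tri-nucleotide or longer units) —
#'     recorded, and gating only when `prefer_longer_motifs` is set.
#' }
#'
#' @param a,b single marker rows (see [read_marker_table()]).
#' @param params a [design_params()] object.
#' @return list with `ok` (all gates pass) and `criteria`, a named logical
#'   record of each criterion.
#' @export
duplex_compatible <- function(a, b, params = design_params()) {
  crit <- c(size_separation = NA, amplification_quality = NA,
            polymorphism_recorded = NA, two_band_disomic = NA,
            map_distance = NA, motif_preference = NA)
  crit["size_separation"] <- range_gap(a, b) >= params$min_gap_bp
  meta_flag <- function(row, col) {
    if (col %in% names(row) && !is.na(row[[col]])) as.logical(row[[col]]) else TRUE
  }
  crit["amplification_quality"] <- meta_flag(a, "quality_ok") && meta_flag(b, "quality_ok")
  crit["two_band_disomic"] <- meta_flag(a, "disomic_ok") && meta_flag(b, "disomic_ok")
  crit["polymorphism_recorded"] <- !is.na(a$pic) && !is.na(b$pic)
  lg_a <- if ("lg_primary" %in% names(a)) a$lg_primary else sub(",.*$", "", a$linkage_group)
  lg_b <- if ("lg_primary" %in% names(b)) b$lg_primary else sub(",.*$", "", b$linkage_group)
  if (is.na(lg_a) || is.na(lg_b)) stop("map_distance criterion needs linkage_group on both markers")
  if (lg_a != lg_b) {
    crit["map_distance"] <- TRUE
  } else {
    if (is.na(a$position_cm) || is.na(b$position_cm)) {
      stop("map_distance criterion needs position_cm for same-group markers")
    }
    crit["map_distance"] <- abs(a$position_cm - b$position_cm) >= params$min_cm
  }
  longer <- function(row) {
    if (is.na(row$motif) || row$motif == "") return(NA)
    u <- classify_motif(row$motif)$unit_length
    !is.na(u) && u >= 3
  }
  crit["motif_preference"] <- isTRUE(longer(a)) && isTRUE(longer(b))
  gates <- crit[c("size_separation", "amplification_quality",
                  "two_band_disomic", "map_distance")]
  if (params$prefer_longer_motifs) gates <- c(gates, crit["motif_preference"])
  list(ok = all(gates), criteria = crit)
}

#' Assemble markers into duplex sets
#'
#' Builds the pairwise compatibility graph under [duplex_compatible()] and
#' selects a matching (each marker in at most one duplex). The default
#' method is exact maximum-weight matching with weight `pic_a + pic_b`,
#' which operationalizes the size-separation, polymorphism and map-distance
#' criteria in one reproducible optimization; `"greedy"` pairs markers in
#' descending-PIC order as a faster, order-transparent alternative. Markers
#' are processed in lexicographic id order, so ties resolve
#' deterministically.
#'
#' @param markers marker table (needs `id`, size range, linkage group,
#'   `pic` for the default objective).
#' @param params a [design_params()].
#' @param method `"matching"` (exact) or `"greedy"`.
#' @return data.frame of duplex sets: `set`, `marker_a`, `marker_b`
#'   (lexicographic within a pair), `d_min_bp` (range-based gap), `same_lg`,
#'   `cm_distance` (within-group distance, `NA` across groups),
#'   `total_pic`. Unpaired marker ids are attached as attribute
#'   `"unpaired"`.
#' @export
assemble_duplexes <- function(markers, params = design_params(),
                              method = c("matching", "greedy")) {
  method <- match.arg(method)
  if (nrow(markers) < 2) stop("need at least two markers to assemble duplexes")
  markers <- markers[order(markers$id), , drop = FALSE]
  n <- nrow(markers)
  use_pic <- params$objective == "max_total_pic" || method == "greedy"
  if (use_pic && any(is.na(markers$pic))) {
    stop("PIC-weighted assembly needs a pic value for every marker")
  }
  pairs <- utils::combn(n, 2)
  edge <- list()
  for (c0 in seq_len(ncol(pairs))) {
    ia <- pairs[1, c0]; ib <- pairs[2, c0]
    comp <- duplex_compatible(markers[ia, , drop = FALSE],
                              markers[ib, , drop = FALSE], params)
    if (comp$ok) {
      w <- markers$pic[ia] + markers$pic[ib]
      if (params$objective == "max_pairs") w <- 1000 + w
      edge[[length(edge) + 1]] <- c(ia, ib, w)
    }
  }
  if (!length(edge)) {
    out <- duplex_frame(markers, integer(0), integer(0))
    attr(out, "unpaired") <- markers$id
    return(out)
  }
  E <- as.data.frame(do.call(rbind, edge))
  names(E) <- c("i", "j", "w")
  if (method == "matching") {
    mate <- max_weight_matching(n, E)
    ia <- which(mate > seq_len(n))
    ib <- mate[ia]
  } else {
    mate <- integer(n)
    adj_w <- matrix(-Inf, n, n)
    for (r in seq_len(nrow(E))) {
      adj_w[E$i[r], E$j[r]] <- adj_w[E$j[r], E$i[r]] <- markers$pic[E$i[r]] + markers$pic[E$j[r]]
    }
    ord <- order(-markers$pic, markers$id)
    for (v in ord) {
      if (mate[v] > 0) next
      cand <- which(adj_w[v, ] > -Inf & mate == 0 & seq_len(n) != v)
      if (!length(cand)) next
      best <- cand[order(-adj_w[v, cand], markers$id[cand])][1]
      mate[v] <- best; mate[best] <- v
    }
    ia <- which(mate > seq_len(n))
    ib <- mate[ia]
  }
  out <- duplex_frame(markers, ia, ib)
  attr(out, "unpaired") <- setdiff(markers$id, c(out$marker_a, out$marker_b))
  out
}

duplex_frame <- function(markers, ia, ib) {
  if (!length(ia)) {
    return(data.frame(set = integer(0), marker_a = character(0),
                      marker_b = character(0), d_min_bp = numeric(0),
                      same_lg = logical(0), cm_distance = numeric(0),
                      total_pic = numeric(0), stringsAsFactors = FALSE))
  }
  swap <- markers$id[ia] > markers$id[ib]
  tmp <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- tmp
  ord <- order(markers$id[ia])
  ia <- ia[ord]; ib <- ib[ord]
  lg <- function(i) {
    if ("lg_primary" %in% names(markers)) markers$lg_primary[i]
    else sub(",.*$", "", markers$linkage_group[i])
  }
  same <- lg(ia) == lg(ib)
  data.frame(
    set = seq_along(ia),
    marker_a = markers$id[ia], marker_b = markers$id[ib],
    d_min_bp = vapply(seq_along(ia), function(r) {
      range_gap(markers[ia[r], , drop = FALSE], markers[ib[r], , drop = FALSE])
    }, numeric(1)),
    same_lg = same,
    cm_distance = ifelse(same, abs(markers$position_cm[ia] - markers$position_cm[ib]), NA_real_),
    total_pic = markers$pic[ia] + markers$pic[ib],
    stringsAsFactors = FALSE)
}

#' Range-based gap of every declared duplex set in a marker table
#'
#' Recomputes the band-range separation for each duplex set already declared
#' in a marker table (its `duplex_set` column) — the panel-audit companion
#' to [assemble_duplexes()].
#'
#' @param markers marker table with a `duplex_set` column pairing the rows.
#' @return data.frame: `set`, `marker_a`, `marker_b`, `gap_bp`,
#'   `printed_d_min_bp` (the table's own `d_min_bp`, if any).
#' @export
duplex_set_gaps <- function(markers) {
  if (!"duplex_set" %in% names(markers) || all(is.na(markers$duplex_set))) {
    stop("marker table has no duplex_set assignments")
  }
  sets <- sort(unique(markers$duplex_set[!is.na(markers$duplex_set)]))
  rows <- lapply(sets, function(s) {
    mm <- markers[!is.na(markers$duplex_set) & markers$duplex_set == s, , drop = FALSE]
    if (nrow(mm) != 2) stop("duplex set ", s, " has ", nrow(mm), " markers (expected 2)")
    data.frame(set = s, marker_a = mm$id[1], marker_b = mm$id[2],
               gap_bp = range_gap(mm[1, ], mm[2, ]),
               printed_d_min_bp = if (any(!is.na(mm$d_min_bp))) mm$d_min_bp[!is.na(mm$d_min_bp)][1] else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Marker distribution along the linkage map
#'
#' Sorts markers by position within each (primary) linkage group and
#' reports adjacent-marker distances: per-group counts, gaps and mean gap,
#' plus the global mean over all adjacent gaps. Groups with fewer than two
#' markers contribute no gaps.
#'
#' @param markers marker table with linkage-group and `position_cm` columns.
#' @return list with `per_lg` (data.frame: `lg`, `n_markers`, `mean_gap_cm`),
#'   `gaps` (named list of per-group adjacent distances) and
#'   `global_mean_gap_cm`.
#' @export
map_distribution <- function(markers) {
  lg <- if ("lg_primary" %in% names(markers)) markers$lg_primary
        else sub(",.*$", "", markers$linkage_group)
  if (any(is.na(lg)) || any(is.na(markers$position_cm))) {
    stop("map_distribution needs linkage group and position for every marker")
  }
  groups <- split(markers$position_cm, lg)
  gaps <- lapply(groups, function(pos) {
    if (length(pos) < 2) numeric(0) else diff(sort(pos))
  })
  per_lg <- data.frame(
    lg = names(groups),
    n_markers = vapply(groups, length, integer(1)),
    mean_gap_cm = vapply(gaps, function(g) if (length(g)) mean(g) else NA_real_, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  all_gaps <- unlist(gaps, use.names = FALSE)
  list(per_lg = per_lg, gaps = gaps,
       global_mean_gap_cm = if (length(all_gaps)) mean(all_gaps) else NA_real_)
}
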