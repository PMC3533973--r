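# shared fixtures and independent oracles, all built in code

table2_path <- function() duplexssr_example("table2_markers.tsv")
table3_path <- function() duplexssr_example("table3_families.tsv")

# small hand-built family: mother K4 {161,189} / {203,230}, three progeny
toy_panel <- function() {
  ind <- data.frame(
    id = c("K4", "K4-01", "K4-02", "K4-03"),
    mother_id = c(NA, "K4", "K4", "K4"))
  markers <- data.frame(id = c("LocA", "LocB"))
  a1 <- rbind(c("161", "203"),
              c("161", "203"),
              c("161", "205"),
              c("140", "250"))
  a2 <- rbind(c("189", "230"),
              c("189", "230"),
              c("189", "230"),
              c("150", "260"))
  genotype_panel(ind, markers, a1, a2)
}

# random panel with band-size labels, occasional homozygotes and missing cells
random_panel <- function(seed, n_ind = 6, n_loci = 4) {
  set.seed(seed)
  ids <- sprintf("I%02d", seq_len(n_ind))
  loci <- sprintf("X%d", seq_len(n_loci))
  a1 <- matrix(NA_character_, n_ind, n_loci)
  a2 <- a1
  for (j in seq_len(n_loci)) {
    sizes <- as.character(seq(100 + 20 * j, by = 2, length.out = 6))
    for (i in seq_len(n_ind)) {
      if (runif(1) < 0.15) next
      g <- sample(sizes, 2, replace = TRUE)
      a1[i, j] <- g[1]; a2[i, j] <- g[2]
    }
  }
  genotype_panel(data.frame(id = ids), data.frame(id = loci), a1, a2)
}

panels_equal <- function(p, q) {
  identical(p$individuals$id, q$individuals$id) &&
    identical(p$markers$id, q$markers$id) &&
    identical(unname(p$allele1), unname(q$allele1)) &&
    identical(unname(p$allele2), unname(q$allele2))
}

# exhaustive maximum-weight-matching oracle (independent of the blossom code)
brute_force_matching <- function(n, edges) {
  best <- 0
  E <- as.data.frame(edges)
  rec <- function(avail, total) {
    best <<- max(best, total)
    if (!length(avail)) return()
    v <- avail[1]
    rec(avail[-1], total)
    for (r in seq_len(nrow(E))) {
      a <- E$i[r]; b <- E$j[r]
      if ((a == v && b %in% avail) || (b == v && a %in% avail)) {
        rec(setdiff(avail, c(a, b)), total + E$w[r])
      }
    }
  }
  rec(seq_len(n), 0)
  best
}

# Dirichlet draw for property tests
rdirichlet1 <- function(k, conc = 1) {
  repeat {
    g <- rgamma(k, shape = conc)
    if (sum(g) > 0 && all(g / sum(g) > 0)) return(g / sum(g))
  }
}

# random marker table for assembly stress tests
random_marker_table <- function(seed, n) {
  set.seed(seed)
  lo <- sample(100:300, n, replace = TRUE)
  data.frame(
    id = sprintf("R%02d", seq_len(n)),
    size_min_bp = lo,
    size_max_bp = lo + sample(10:60, n, replace = TRUE),
    linkage_group = sample(sprintf("%d%s", 1:5, "a"), n, replace = TRUE),
    lg_primary = NA_character_,
    position_cm = round(runif(n, 0, 120), 1),
    pic = round(runif(n, 0.3, 0.95), 3),
    motif = "(CAG)8",
    stringsAsFactors = FALSE) -> m
  m$lg_primary <- m$linkage_group
  m
}
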