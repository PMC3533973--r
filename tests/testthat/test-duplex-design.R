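mk <- function(id, lo, hi, lg = "1a", pos = 10, pic = 0.8, motif = "(CAG)8") {
  data.frame(id = id, size_min_bp = lo, size_max_bp = hi,
             linkage_group = lg, lg_primary = lg, position_cm = pos,
             pic = pic, motif = motif, stringsAsFactors = FALSE)
}

test_that("range gap is the separation of the two size ranges, symmetric", {
  a <- mk("A", 211, 293); b <- mk("B", 156, 195)
  expect_equal(range_gap(a, b), 16)
  expect_equal(range_gap(b, a), 16)
  expect_equal(range_gap(mk("A", 229, 337), mk("B", 163, 226)), 3)
  expect_equal(range_gap(mk("A", 100, 200), mk("B", 150, 250)), -50)
  expect_error(range_gap(mk("A", NA, NA), b), "size_min_bp")
})

test_that("observed separation uses the bands actually scored", {
  p <- genotype_panel(data.frame(id = c("i1", "i2")),
                      data.frame(id = c("A", "B")),
                      rbind(c("161", "234"), c("161", "234")),
                      rbind(c("161", "234"), c("161", "234")))
  expect_equal(observed_min_separation(p, "A", "B"), 73)
  q <- genotype_panel(data.frame(id = "i1"), data.frame(id = c("A", "B")),
                      rbind(c("100", "100")), rbind(c("100", "110")))
  expect_equal(observed_min_separation(q, "A", "B"), 0)
  r <- genotype_panel(data.frame(id = "i1"), data.frame(id = c("A", "B")),
                      rbind(c("100", "110")), rbind(c("100", "110")))
  expect_equal(observed_min_separation(r, "A", "B"), 10)
})

test_that("observed separation is at least the range gap for disjoint ranges", {
  set.seed(5)
  for (rep in 1:20) {
    lo1 <- sample(100:150, 1); hi1 <- lo1 + sample(5:30, 1)
    lo2 <- hi1 + sample(1:40, 1); hi2 <- lo2 + sample(5:30, 1)
    b1 <- as.character(sample(lo1:hi1, 3, replace = TRUE))
    b2 <- as.character(sample(lo2:hi2, 3, replace = TRUE))
    p <- genotype_panel(data.frame(id = c("x", "y", "z")),
                        data.frame(id = c("A", "B")),
                        cbind(b1, b2), cbind(b1, b2))
    gap <- range_gap(mk("A", lo1, hi1), mk("B", lo2, hi2))
    expect_gte(observed_min_separation(p, "A", "B"), gap)
  }
})

test_that("compatibility gates: band separation and map distance", {
  params <- design_params()
  # different linkage groups, 24-bp gap: compatible
  a <- mk("PVCAG-2397/8", 161, 189, lg = "3b", pos = 36.3, pic = 0.822)
  b <- mk("PVCAG-2517/8", 213, 234, lg = "9a", pos = 6.9, pic = 0.879)
  res <- duplex_compatible(a, b, params)
  expect_true(res$ok)
  expect_true(all(res$criteria[c("size_separation", "map_distance")]))
  # 3-bp gap fails the separation criterion
  res15 <- duplex_compatible(mk("A", 229, 337, lg = "5a", pos = 59.5),
                             mk("B", 163, 226, lg = "9b", pos = 50.5), params)
  expect_false(res15$ok)
  expect_false(res15$criteria[["size_separation"]])
  # same group, 5 cM apart: fails map distance
  res5 <- duplex_compatible(mk("A", 100, 120, lg = "2b", pos = 10),
                            mk("B", 150, 170, lg = "2b", pos = 15), params)
  expect_false(res5$ok)
  expect_false(res5$criteria[["map_distance"]])
  # same group but >= 10 cM passes
  expect_true(duplex_compatible(mk("A", 100, 120, lg = "2b", pos = 10),
                                mk("B", 150, 170, lg = "2b", pos = 25), params)$ok)
})

test_that("motif preference records unit length and can gate", {
  di <- mk("A", 100, 120, lg = "1a", motif = "(TG)12")
  tri <- mk("B", 150, 170, lg = "2a", motif = "(CAG)8")
  tri2 <- mk("C", 200, 220, lg = "3a", motif = "(GCT)9")
  lax <- design_params()
  strict <- design_params(prefer_longer_motifs = TRUE)
  expect_true(duplex_compatible(di, tri, lax)$ok)
  expect_false(duplex_compatible(di, tri, strict)$ok)
  expect_true(duplex_compatible(tri, tri2, strict)$ok)
})

test_that("assembly pairs compatible markers and maximizes total PIC", {
  two <- rbind(mk("A", 100, 120, lg = "1a", pic = 0.9),
               mk("B", 150, 170, lg = "2a", pic = 0.8))
  d <- assemble_duplexes(two)
  expect_equal(nrow(d), 1L)
  expect_equal(c(d$marker_a, d$marker_b), c("A", "B"))
  expect_equal(d$d_min_bp, 30)
  # three mutually compatible markers: the top-PIC pair is kept
  three <- rbind(mk("A", 100, 120, lg = "1a", pic = 0.9),
                 mk("B", 150, 170, lg = "2a", pic = 0.8),
                 mk("C", 200, 220, lg = "3a", pic = 0.2))
  d3 <- assemble_duplexes(three)
  expect_equal(nrow(d3), 1L)
  expect_equal(sort(c(d3$marker_a, d3$marker_b)), c("A", "B"))
  expect_equal(attr(d3, "unpaired"), "C")
})

test_that("assembly output is a valid matching attaining the brute-force optimum", {
  params <- design_params()
  for (seed in 1:12) {
    m <- random_marker_table(seed, n = sample(4:8, 1))
    d <- assemble_duplexes(m, params)
    used <- c(d$marker_a, d$marker_b)
    expect_equal(anyDuplicated(used), 0L)
    # independent oracle over the same compatibility graph
    n <- nrow(m); m <- m[order(m$id), ]
    edges <- list()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (duplex_compatible(m[i, ], m[j, ], params)$ok) {
        edges[[length(edges) + 1]] <- data.frame(i = i, j = j,
                                                 w = m$pic[i] + m$pic[j])
      }
    }
    opt <- if (length(edges)) brute_force_matching(n, do.call(rbind, edges)) else 0
    expect_equal(sum(d$total_pic), opt, tolerance = 1e-9,
                 info = paste("seed", seed))
  }
})

test_that("declared duplex sets audit against the packaged marker table", {
  m <- read_marker_table(table2_path())
  g <- duplex_set_gaps(m)
  expect_equal(nrow(g), 24L)
  # the recomputed range gap reproduces the printed separation for 23 of 24
  # sets; the one exception records an observed-call separation instead
  agree <- g$gap_bp == g$printed_d_min_bp
  expect_equal(sum(agree), 23L)
  expect_equal(g$set[!agree], 2)
})

test_that("map distribution sorts within groups and averages adjacent gaps", {
  m <- rbind(mk("A", 1, 2, lg = "9b", pos = 34.1), mk("B", 3, 4, lg = "9b", pos = 76.4),
             mk("C", 5, 6, lg = "9b", pos = 46.5), mk("D", 7, 8, lg = "9b", pos = 50.5),
             mk("E", 9, 10, lg = "1a", pos = 12))
  md <- map_distribution(m)
  expect_equal(md$gaps[["9b"]], c(12.4, 4.0, 25.9))
  expect_equal(round_half_up(md$per_lg$mean_gap_cm[md$per_lg$lg == "9b"], 1), 14.1)
  # a single-marker group contributes no gaps
  expect_length(md$gaps[["1a"]], 0)
  expect_true(is.na(md$per_lg$mean_gap_cm[md$per_lg$lg == "1a"]))
  expect_equal(md$global_mean_gap_cm, mean(c(12.4, 4.0, 25.9)))
})
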