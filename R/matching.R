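#' Maximum-weight matching in a general graph
#'
#' Exact maximum-weight matching by the primal-dual blossom method
#' (Galil's O(n^3) formulation, following van Rantwijk's widely used
#' implementation). Works on arbitrary (non-bipartite) graphs, which is what
#' marker-pairing needs: any two compatible loci may be paired, so the
#' compatibility graph has odd cycles.
#'
#' @param n_vertices number of vertices, labelled `1..n`.
#' @param edges matrix or data.frame with columns `i`, `j` (vertex indices,
#'   `i != j`) and `w` (edge weight). Parallel edges are allowed (the best
#'   one wins); only edges listed can be matched.
#' @return Integer vector `mate` of length `n_vertices`: `mate[v]` is the
#'   partner of `v`, or `0` if `v` is unmatched. The solution maximizes the
#'   total weight of matched edges.
#' @export
max_weight_matching <- function(n_vertices, edges) {
  edges <- as.data.frame(edges)
  if (!all(c("i", "j", "w") %in% names(edges))) {
    stop("edges needs columns i, j, w")
  }
  if (!nrow(edges)) return(integer(n_vertices))
  if (any(edges$i == edges$j)) stop("self-loops are not allowed")
  if (any(edges$i < 1 | edges$j < 1 | edges$i > n_vertices | edges$j > n_vertices)) {
    stop("edge endpoint outside 1..n_vertices")
  }
  # internal state is 0-based to keep the endpoint xor arithmetic intact
  ei <- as.integer(edges$i) - 1L
  ej <- as.integer(edges$j) - 1L
  ew <- as.numeric(edges$w)
  nedge <- length(ei)
  nvertex <- as.integer(n_vertices)
  maxweight <- max(0, ew)

  # endpoint[p+1], p in 0..2*nedge-1: p = 2k -> i of edge k, p = 2k+1 -> j
  endpoint <- integer(2L * nedge)
  endpoint[2L * seq_len(nedge) - 1L] <- ei
  endpoint[2L * seq_len(nedge)] <- ej
  neighbend <- vector("list", nvertex)  # endpoints p with endpoint[xor(p,1)] == v
  for (k in seq_len(nedge)) {
    neighbend[[ei[k] + 1L]] <- c(neighbend[[ei[k] + 1L]], 2L * (k - 1L) + 1L)
    neighbend[[ej[k] + 1L]] <- c(neighbend[[ej[k] + 1L]], 2L * (k - 1L))
  }

  mate <- rep(-1L, nvertex)
  label <- integer(2L * nvertex)
  labelend <- rep(-1L, 2L * nvertex)
  inblossom <- seq_len(nvertex) - 1L
  blossomparent <- rep(-1L, 2L * nvertex)
  blossomchilds <- vector("list", 2L * nvertex)
  blossombase <- c(seq_len(nvertex) - 1L, rep(-1L, nvertex))
  blossomendps <- vector("list", 2L * nvertex)
  bestedge <- rep(-1L, 2L * nvertex)
  blossombestedges <- vector("list", 2L * nvertex)
  unusedblossoms <- seq.int(nvertex, 2L * nvertex - 1L)
  dualvar <- c(rep(maxweight, nvertex), rep(0, nvertex))
  allowedge <- rep(FALSE, nedge)
  queue <- integer(0)

  opp <- function(p) bitwXor(p, 1L)

  slack <- function(k) {
    dualvar[ei[k + 1L] + 1L] + dualvar[ej[k + 1L] + 1L] - 2 * ew[k + 1L]
  }

  blossom_leaves <- function(b) {
    if (b < nvertex) return(b)
    unlist(lapply(blossomchilds[[b + 1L]], blossom_leaves))
  }

  assign_label <- function(w, t, p) {
    b <- inblossom[w + 1L]
    stopifnot(label[w + 1L] == 0, label[b + 1L] == 0)
    label[w + 1L] <<- t; label[b + 1L] <<- t
    labelend[w + 1L] <<- p; labelend[b + 1L] <<- p
    bestedge[w + 1L] <<- -1L; bestedge[b + 1L] <<- -1L
    if (t == 1L) {
      queue <<- c(queue, blossom_leaves(b))
    } else if (t == 2L) {
      base <- blossombase[b + 1L]
      stopifnot(mate[base + 1L] >= 0)
      assign_label(endpoint[mate[base + 1L] + 1L], 1L, opp(mate[base + 1L]))
    }
  }

  scan_blossom <- function(v, w) {
    # trace back from v and w to find a common ancestor (new blossom base)
    path <- integer(0)
    base <- -1L
    while (v != -1L || w != -1L) {
      b <- inblossom[v + 1L]
      if (bitwAnd(label[b + 1L], 4L) != 0L) {
        base <- blossombase[b + 1L]
        break
      }
      stopifnot(label[b + 1L] == 1L)
      path <- c(path, b)
      label[b + 1L] <<- 5L
      if (labelend[b + 1L] == -1L) {
        v <- -1L
      } else {
        v <- endpoint[labelend[b + 1L] + 1L]
        b <- inblossom[v + 1L]
        stopifnot(label[b + 1L] == 2L)
        v <- endpoint[labelend[b + 1L] + 1L]
      }
      if (w != -1L) { tmp <- v; v <- w; w <- tmp }
    }
    for (b in path) label[b + 1L] <<- 1L
    base
  }

  add_blossom <- function(base, k) {
    v <- ei[k + 1L]; w <- ej[k + 1L]
    bb <- inblossom[base + 1L]
    bv <- inblossom[v + 1L]
    bw <- inblossom[w + 1L]
    b <- unusedblossoms[length(unusedblossoms)]
    unusedblossoms <<- unusedblossoms[-length(unusedblossoms)]
    blossombase[b + 1L] <<- base
    blossomparent[b + 1L] <<- -1L
    blossomparent[bb + 1L] <<- b
    path <- integer(0); endps <- integer(0)
    while (bv != bb) {
      blossomparent[bv + 1L] <<- b
      path <- c(path, bv)
      endps <- c(endps, labelend[bv + 1L])
      stopifnot(labelend[bv + 1L] >= 0)
      v <- endpoint[labelend[bv + 1L] + 1L]
      bv <- inblossom[v + 1L]
    }
    path <- rev(c(path, bb))
    endps <- c(rev(endps), 2L * k)
    while (bw != bb) {
      blossomparent[bw + 1L] <<- b
      path <- c(path, bw)
      endps <- c(endps, opp(labelend[bw + 1L]))
      stopifnot(labelend[bw + 1L] >= 0)
      w <- endpoint[labelend[bw + 1L] + 1L]
      bw <- inblossom[w + 1L]
    }
    blossomchilds[[b + 1L]] <<- path
    blossomendps[[b + 1L]] <<- endps
    stopifnot(label[bb + 1L] == 1L)
    label[b + 1L] <<- 1L
    labelend[b + 1L] <<- labelend[bb + 1L]
    dualvar[b + 1L] <<- 0
    for (lv in blossom_leaves(b)) {
      if (label[inblossom[lv + 1L] + 1L] == 2L) queue <<- c(queue, lv)
      inblossom[lv + 1L] <<- b
    }
    bestedgeto <- rep(-1L, 2L * nvertex)
    for (bv in path) {
      if (is.null(blossombestedges[[bv + 1L]])) {
        nblist <- unique(unlist(lapply(blossom_leaves(bv), function(lv) {
          neighbend[[lv + 1L]] %/% 2L
        })))
      } else {
        nblist <- blossombestedges[[bv + 1L]]
      }
      for (kk in nblist) {
        ii <- ei[kk + 1L]; jj <- ej[kk + 1L]
        if (inblossom[jj + 1L] == b) { tmp <- ii; ii <- jj; jj <- tmp }
        bj <- inblossom[jj + 1L]
        if (bj != b && label[bj + 1L] == 1L &&
            (bestedgeto[bj + 1L] == -1L || slack(kk) < slack(bestedgeto[bj + 1L]))) {
          bestedgeto[bj + 1L] <- kk
        }
      }
      blossombestedges[bv + 1L] <<- list(NULL)
      bestedge[bv + 1L] <<- -1L
    }
    keep <- bestedgeto[bestedgeto != -1L]
    blossombestedges[[b + 1L]] <<- keep
    be <- -1L
    for (kk in keep) {
      if (be == -1L || slack(kk) < slack(be)) be <- kk
    }
    bestedge[b + 1L] <<- be
  }

  expand_blossom <- function(b, endstage) {
    for (s in blossomchilds[[b + 1L]]) {
      blossomparent[s + 1L] <<- -1L
      if (s < nvertex) {
        inblossom[s + 1L] <<- s
      } else if (endstage && dualvar[s + 1L] == 0) {
        expand_blossom(s, endstage)
      } else {
        for (lv in blossom_leaves(s)) inblossom[lv + 1L] <<- s
      }
    }
    if (!endstage && label[b + 1L] == 2L) {
      stopifnot(labelend[b + 1L] >= 0)
      entrychild <- inblossom[endpoint[opp(labelend[b + 1L]) + 1L] + 1L]
      childs <- blossomchilds[[b + 1L]]
      endps <- blossomendps[[b + 1L]]
      j <- which(childs == entrychild)[1] - 1L  # 0-based index
      if (bitwAnd(j, 1L) != 0L) {
        j <- j - length(childs)
        jstep <- 1L; endptrick <- 0L
      } else {
        jstep <- -1L; endptrick <- 1L
      }
      ep <- function(idx) endps[((idx %% length(endps)) + 1L)]  # python negative index
      p <- labelend[b + 1L]
      while (j != 0L) {
        label[endpoint[opp(p) + 1L] + 1L] <<- 0L
        label[endpoint[opp(bitwXor(ep(j - endptrick), endptrick)) + 1L] + 1L] <<- 0L
        assign_label(endpoint[opp(p) + 1L], 2L, p)
        allowedge[ep(j - endptrick) %/% 2L + 1L] <<- TRUE
        j <- j + jstep
        p <- bitwXor(ep(j - endptrick), endptrick)
        allowedge[p %/% 2L + 1L] <<- TRUE
        j <- j + jstep
      }
      bv <- childs[(j %% length(childs)) + 1L]
      label[endpoint[opp(p) + 1L] + 1L] <<- 2L
      label[bv + 1L] <<- 2L
      labelend[endpoint[opp(p) + 1L] + 1L] <<- p
      labelend[bv + 1L] <<- p
      bestedge[bv + 1L] <<- -1L
      j <- j + jstep
      while (childs[(j %% length(childs)) + 1L] != entrychild) {
        bv <- childs[(j %% length(childs)) + 1L]
        if (label[bv + 1L] == 1L) { j <- j + jstep; next }
        lv <- -1L
        for (cand in blossom_leaves(bv)) {
          lv <- cand
          if (label[cand + 1L] != 0L) break
        }
        if (lv >= 0 && label[lv + 1L] != 0L) {
          stopifnot(label[lv + 1L] == 2L, inblossom[lv + 1L] == bv)
          label[lv + 1L] <<- 0L
          label[endpoint[mate[blossombase[bv + 1L] + 1L] + 1L] + 1L] <<- 0L
          assign_label(lv, 2L, labelend[lv + 1L])
        }
        j <- j + jstep
      }
    }
    label[b + 1L] <<- -1L
    labelend[b + 1L] <<- -1L
    blossomchilds[b + 1L] <<- list(NULL)
    blossomendps[b + 1L] <<- list(NULL)
    blossombase[b + 1L] <<- -1L
    blossombestedges[b + 1L] <<- list(NULL)
    bestedge[b + 1L] <<- -1L
    unusedblossoms <<- c(unusedblossoms, b)
  }

  augment_blossom <- function(b, v) {
    t <- v
    while (blossomparent[t + 1L] != b) t <- blossomparent[t + 1L]
    if (t >= nvertex) augment_blossom(t, v)
    childs <- blossomchilds[[b + 1L]]
    endps <- blossomendps[[b + 1L]]
    i <- which(childs == t)[1] - 1L
    j <- i
    if (bitwAnd(i, 1L) != 0L) {
      j <- j - length(childs)
      jstep <- 1L; endptrick <- 0L
    } else {
      jstep <- -1L; endptrick <- 1L
    }
    ep <- function(idx) endps[((idx %% length(endps)) + 1L)]
    ch <- function(idx) childs[((idx %% length(childs)) + 1L)]
    while (j != 0L) {
      j <- j + jstep
      t <- ch(j)
      p <- bitwXor(ep(j - endptrick), endptrick)
      if (t >= nvertex) augment_blossom(t, endpoint[p + 1L])
      j <- j + jstep
      t <- ch(j)
      if (t >= nvertex) augment_blossom(t, endpoint[opp(p) + 1L])
      mate[endpoint[p + 1L] + 1L] <<- opp(p)
      mate[endpoint[opp(p) + 1L] + 1L] <<- p
    }
    rot <- function(x, k) if (k == 0L) x else c(x[(k + 1L):length(x)], x[1:k])
    blossomchilds[[b + 1L]] <<- rot(childs, i)
    blossomendps[[b + 1L]] <<- rot(endps, i)
    blossombase[b + 1L] <<- blossombase[blossomchilds[[b + 1L]][1] + 1L]
    stopifnot(blossombase[b + 1L] == v)
  }

  augment_matching <- function(k) {
    v <- ei[k + 1L]; w <- ej[k + 1L]
    starts <- list(c(v, 2L * k + 1L), c(w, 2L * k))
    for (sp in starts) {
      s <- sp[1]; p <- sp[2]
      repeat {
        bs <- inblossom[s + 1L]
        stopifnot(label[bs + 1L] == 1L)
        if (bs >= nvertex) augment_blossom(bs, s)
        mate[s + 1L] <<- p
        if (labelend[bs + 1L] == -1L) break
        t <- endpoint[labelend[bs + 1L] + 1L]
        bt <- inblossom[t + 1L]
        stopifnot(label[bt + 1L] == 2L, labelend[bt + 1L] >= 0)
        s <- endpoint[labelend[bt + 1L] + 1L]
        j <- endpoint[opp(labelend[bt + 1L]) + 1L]
        stopifnot(blossombase[bt + 1L] == t)
        if (bt >= nvertex) augment_blossom(bt, j)
        mate[j + 1L] <<- labelend[bt + 1L]
        p <- opp(labelend[bt + 1L])
      }
    }
  }

  for (stage in seq_len(nvertex)) {
    label[] <- 0L
    bestedge[] <- -1L
    for (b in seq.int(nvertex, 2L * nvertex - 1L)) blossombestedges[b + 1L] <- list(NULL)
    allowedge[] <- FALSE
    queue <- integer(0)
    for (v in seq_len(nvertex) - 1L) {
      if (mate[v + 1L] == -1L && label[inblossom[v + 1L] + 1L] == 0L) {
        assign_label(v, 1L, -1L)
      }
    }
    augmented <- FALSE
    repeat {
      while (length(queue) && !augmented) {
        v <- queue[length(queue)]
        queue <- queue[-length(queue)]
        stopifnot(label[inblossom[v + 1L] + 1L] == 1L)
        for (p in neighbend[[v + 1L]]) {
          k <- p %/% 2L
          w <- endpoint[p + 1L]
          if (inblossom[v + 1L] == inblossom[w + 1L]) next
          kslack <- NA_real_
          if (!allowedge[k + 1L]) {
            kslack <- slack(k)
            if (kslack <= 0) allowedge[k + 1L] <- TRUE
          }
          if (allowedge[k + 1L]) {
            if (label[inblossom[w + 1L] + 1L] == 0L) {
              assign_label(w, 2L, opp(p))
            } else if (label[inblossom[w + 1L] + 1L] == 1L) {
              base <- scan_blossom(v, w)
              if (base >= 0) {
                add_blossom(base, k)
              } else {
                augment_matching(k)
                augmented <- TRUE
                break
              }
            } else if (label[w + 1L] == 0L) {
              stopifnot(label[inblossom[w + 1L] + 1L] == 2L)
              label[w + 1L] <- 2L
              labelend[w + 1L] <- opp(p)
            }
          } else if (label[inblossom[w + 1L] + 1L] == 1L) {
            b <- inblossom[v + 1L]
            if (bestedge[b + 1L] == -1L || kslack < slack(bestedge[b + 1L])) {
              bestedge[b + 1L] <- k
            }
          } else if (label[w + 1L] == 0L) {
            if (bestedge[w + 1L] == -1L || kslack < slack(bestedge[w + 1L])) {
              bestedge[w + 1L] <- k
            }
          }
        }
      }
      if (augmented) break

      deltatype <- 1L
      delta <- min(dualvar[seq_len(nvertex)])
      deltaedge <- -1L; deltablossom <- -1L
      for (v in seq_len(nvertex) - 1L) {
        if (label[inblossom[v + 1L] + 1L] == 0L && bestedge[v + 1L] != -1L) {
          d <- slack(bestedge[v + 1L])
          if (d < delta) { delta <- d; deltatype <- 2L; deltaedge <- bestedge[v + 1L] }
        }
      }
      for (b in seq_len(2L * nvertex) - 1L) {
        if (blossomparent[b + 1L] == -1L && label[b + 1L] == 1L &&
            bestedge[b + 1L] != -1L) {
          d <- slack(bestedge[b + 1L]) / 2
          if (d < delta) { delta <- d; deltatype <- 3L; deltaedge <- bestedge[b + 1L] }
        }
      }
      for (b in seq.int(nvertex, 2L * nvertex - 1L)) {
        if (blossombase[b + 1L] >= 0 && blossomparent[b + 1L] == -1L &&
            label[b + 1L] == 2L && dualvar[b + 1L] < delta) {
          delta <- dualvar[b + 1L]; deltatype <- 4L; deltablossom <- b
        }
      }

      for (v in seq_len(nvertex) - 1L) {
        lab <- label[inblossom[v + 1L] + 1L]
        if (lab == 1L) dualvar[v + 1L] <- dualvar[v + 1L] - delta
        else if (lab == 2L) dualvar[v + 1L] <- dualvar[v + 1L] + delta
      }
      for (b in seq.int(nvertex, 2L * nvertex - 1L)) {
        if (blossombase[b + 1L] >= 0 && blossomparent[b + 1L] == -1L) {
          if (label[b + 1L] == 1L) dualvar[b + 1L] <- dualvar[b + 1L] + delta
          else if (label[b + 1L] == 2L) dualvar[b + 1L] <- dualvar[b + 1L] - delta
        }
      }

      if (deltatype == 1L) break
      if (deltatype == 2L) {
        allowedge[deltaedge + 1L] <- TRUE
        i <- ei[deltaedge + 1L]; j2 <- ej[deltaedge + 1L]
        if (label[inblossom[i + 1L] + 1L] == 0L) i <- j2
        stopifnot(label[inblossom[i + 1L] + 1L] == 1L)
        queue <- c(queue, i)
      } else if (deltatype == 3L) {
        allowedge[deltaedge + 1L] <- TRUE
        i <- ei[deltaedge + 1L]
        stopifnot(label[inblossom[i + 1L] + 1L] == 1L)
        queue <- c(queue, i)
      } else {
        expand_blossom(deltablossom, FALSE)
      }
    }
    if (!augmented) break
    for (b in seq.int(nvertex, 2L * nvertex - 1L)) {
      if (blossomparent[b + 1L] == -1L && blossombase[b + 1L] >= 0 &&
          label[b + 1L] == 1L && dualvar[b + 1L] == 0) {
        expand_blossom(b, TRUE)
      }
    }
  }

  out <- integer(nvertex)
  for (v in seq_len(nvertex)) {
    if (mate[v] >= 0) out[v] <- endpoint[mate[v] + 1L] + 1L
  }
  out
}
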