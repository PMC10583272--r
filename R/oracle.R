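# Independent brute-force CIP oracle.
#
# A deliberately separate implementation of the chain-assignment contract,
# written against the same rules but sharing no machinery with the
# production path: its own breadth-first distances, its own explicit
# hierarchical-digraph construction (recursive, memoisation-free), its own
# determinant and its own shell bookkeeping.  Used in the test suite to
# cross-validate assignChains()/cipCompare() on small molecules.

.ORACLE_Z <- c(H = 1, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
               CL = 17, SE = 34, BR = 35, I = 53)

#' Brute-force CIP chain assignment (test oracle)
#'
#' Exhaustive recursive hierarchical-digraph evaluation of side-chain
#' priorities, limited to 25 heavy atoms.  Same output contract as
#' [assignChains()].
#'
#' @param g A [MolecularGraph-class] of a single residue.
#' @param backbone Named serial vector from [findBackbone()].
#' @return A [ChainAssignment-class].
#' @export
bruteForceCip <- function(g, backbone) {
  at <- atoms(g)
  heavyIdx <- toupper(at$element) != "H" & !at$isPseudo & !at$isDuplicate
  if (sum(heavyIdx) > 25L)
    stop("oracle size cap exceeded: ", sum(heavyIdx), " heavy atoms")
  heavy <- at[heavyIdx, , drop = FALSE]
  hv <- heavy$serial
  bd <- bonds(g)
  bd <- bd[bd$a %in% hv & bd$b %in% hv, , drop = FALSE]
  nbr <- lapply(setNames(hv, hv), function(s)
    c(bd$b[bd$a == s], bd$a[bd$b == s]))
  ordOf <- function(a, b)
    bd$order[(bd$a == a & bd$b == b) | (bd$a == b & bd$b == a)][1]
  zOf <- setNames(unname(.ORACLE_Z[toupper(heavy$element)]), hv)
  xyz <- lapply(setNames(seq_len(nrow(heavy)), hv), function(i)
    c(heavy$x[i], heavy$y[i], heavy$z[i]))

  ca <- backbone[["ca"]]; bbN <- backbone[["n"]]; bbC <- backbone[["c"]]

  # --- own BFS, paths forbidden through backbone N / C' ------------------
  dist <- setNames(rep(NA_integer_, length(hv)), hv)
  dist[as.character(ca)] <- 0L
  queue <- ca
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur %in% c(bbN, bbC)) next
    for (nb in nbr[[as.character(cur)]]) {
      if (nb %in% c(bbN, bbC)) next
      if (is.na(dist[as.character(nb)])) {
        dist[as.character(nb)] <- dist[as.character(cur)] + 1L
        queue <- c(queue, nb)
      }
    }
  }
  side <- hv[!is.na(dist[as.character(hv)]) & dist[as.character(hv)] > 0]
  if (!length(side)) stop("side chain is empty")

  # --- explicit digraph: list(z, kids = list(...)) -----------------------
  # Phantom kids are appended for multiple bonds (one per extra order on
  # each endpoint) and for aromatic participation (one per atom, element of
  # the heaviest aromatic partner); ring closures become phantom leaves.
  phantomKids <- function(a, skip) {
    out <- list()
    for (nb in nbr[[as.character(a)]]) {
      o <- ordOf(a, nb)
      if (o %in% c(2, 3))
        for (r in seq_len(o - 1))
          out[[length(out) + 1L]] <- list(z = zOf[[as.character(nb)]],
                                          kids = list())
    }
    arp <- nbr[[as.character(a)]][vapply(nbr[[as.character(a)]],
      function(nb) ordOf(a, nb) == 1.5, logical(1))]
    if (length(arp)) {
      zz <- zOf[as.character(arp)]
      out[[length(out) + 1L]] <- list(z = max(zz), kids = list())
    }
    out
  }
  growTree <- function(a, from, path) {
    kids <- phantomKids(a)
    for (nb in nbr[[as.character(a)]]) {
      if (length(from) && nb == from) next
      if (nb %in% path) {
        kids[[length(kids) + 1L]] <- list(z = zOf[[as.character(nb)]],
                                          kids = list())
      } else {
        kids[[length(kids) + 1L]] <- growTree(nb, a, c(path, a))
      }
    }
    list(z = zOf[[as.character(a)]], kids = kids)
  }
  sphereList <- function(tree) {
    out <- list(tree$z)
    level <- list(tree)
    repeat {
      nxt <- unlist(lapply(level, function(nd) nd$kids), recursive = FALSE)
      if (!length(nxt)) break
      out[[length(out) + 1L]] <-
        sort(vapply(nxt, function(nd) nd$z, numeric(1)), decreasing = TRUE)
      level <- nxt
    }
    out
  }
  cmpSpheres <- function(sa, sb) {
    for (d in seq_len(max(length(sa), length(sb)))) {
      va <- if (d <= length(sa)) sa[[d]] else numeric()
      vb <- if (d <= length(sb)) sb[[d]] else numeric()
      m <- max(length(va), length(vb))
      if (!m) next
      va <- c(va, rep(0, m - length(va)))
      vb <- c(vb, rep(0, m - length(vb)))
      for (i in seq_len(m)) {
        if (va[i] > vb[i]) return(-1L)
        if (va[i] < vb[i]) return(1L)
      }
    }
    0L
  }
  det4 <- function(p1, p2, p3, p4) {
    # explicit cofactor expansion of |x y z 1| rows
    m3 <- function(a, b, c)
      a[1] * (b[2] * c[3] - b[3] * c[2]) -
      a[2] * (b[1] * c[3] - b[3] * c[1]) +
      a[3] * (b[1] * c[2] - b[2] * c[1])
    -m3(p2, p3, p4) + m3(p1, p3, p4) - m3(p1, p2, p4) + m3(p1, p2, p3)
  }
  # own distance-profile order for chemically arbitrary choices: sorted
  # squared distances to every real atom, compared lexicographically
  realXYZ <- at[!at$isPseudo & !at$isDuplicate, c("x", "y", "z")]
  profileOrder <- function(ss) {
    key <- lapply(ss, function(s) {
      i <- match(s, at$serial)
      p <- c(at$x[i], at$y[i], at$z[i])
      sort(round((realXYZ$x - p[1])^2 + (realXYZ$y - p[2])^2 +
                 (realXYZ$z - p[3])^2, 6))
    })
    kstr <- vapply(key, function(k) paste(sprintf("%018.6f", k),
                                          collapse = "|"), character(1))
    ss[order(kstr)]
  }
  tetrahedralHere <- function(a) {
    full <- bonds(g)
    psd <- at$serial[at$isPseudo | at$isDuplicate]
    keep <- !(full$a %in% psd | full$b %in% psd)
    sum(full$a[keep] == a | full$b[keep] == a) == 4L
  }

  # --- shell-wise assignment --------------------------------------------
  chain <- setNames(rep(NA_integer_, length(side)), side)
  par <- chain
  nextId <- 1L
  events <- list()
  rankSet <- function(kids, parent, anchor) {
    if (length(kids) == 1L) return(list(order = kids, ties = list()))
    kids <- kids[order(kids)]
    trees <- lapply(kids, function(k) growTree(k, parent, parent))
    sph <- lapply(trees, sphereList)
    nn <- length(kids)
    beats <- integer(nn)
    cm <- matrix(0L, nn, nn)
    for (i in seq_len(nn - 1)) for (j in (i + 1):nn) {
      r <- cmpSpheres(sph[[i]], sph[[j]])
      cm[i, j] <- r; cm[j, i] <- -r
    }
    score <- vapply(seq_len(nn), function(i) sum(cm[i, ] > 0L), 0L)
    ord <- order(score)
    res <- integer(); ties <- list()
    i <- 1L
    while (i <= nn) {
      grp <- ord[i]; j <- i + 1L
      while (j <= nn && cm[ord[i], ord[j]] == 0L) {
        grp <- c(grp, ord[j]); j <- j + 1L
      }
      gk <- kids[grp]
      geomDone <- FALSE
      if (length(grp) == 2L && tetrahedralHere(parent) &&
          length(anchor)) {
        dd <- det4(xyz[[as.character(gk[1])]], xyz[[as.character(gk[2])]],
                   xyz[[as.character(parent)]], xyz[[as.character(anchor)]])
        lens <- prod(vapply(gk, function(k)
          sqrt(sum((xyz[[as.character(k)]] -
                    xyz[[as.character(parent)]])^2)), numeric(1)),
          sqrt(sum((xyz[[as.character(anchor)]] -
                    xyz[[as.character(parent)]])^2)))
        if (abs(dd) >= 1e-9 * lens) {
          if (dd < 0) gk <- rev(gk)
          geomDone <- TRUE
        }
      }
      if (length(grp) >= 2L && !geomDone) gk <- profileOrder(gk)
      if (length(grp) >= 2L)
        ties[[length(ties) + 1L]] <- list(parent = parent, kids = gk)
      res <- c(res, gk)
      i <- j
    }
    list(order = res, ties = ties)
  }
  maxD <- max(dist[as.character(side)])
  for (d in 0:(maxD - 1L)) {
    ps <- if (d == 0L) ca else side[dist[as.character(side)] == d]
    if (d > 0L) ps <- ps[order(chain[as.character(ps)])]
    for (p in ps) {
      kids <- nbr[[as.character(p)]]
      kids <- kids[kids %in% side & dist[as.character(kids)] == d + 1L]
      if (!length(kids)) next
      anchor <- if (d == 0L) bbN else par[[as.character(p)]]
      rk <- rankSet(kids, p, anchor)
      events <- c(events, rk$ties)
      for (i in seq_along(rk$order)) {
        k <- as.character(rk$order[i])
        cand <- if (d == 0L) nextId + i - 1L
                else if (i == 1L) chain[[as.character(p)]] else NA_integer_
        if (is.na(chain[[k]])) {
          if (is.na(cand)) { cand <- nextId; nextId <- nextId + 1L }
          chain[[k]] <- cand; par[[k]] <- p
        } else if (!is.na(cand) && cand < chain[[k]]) {
          chain[[k]] <- cand
        }
      }
      if (d == 0L) nextId <- nextId + length(rk$order)
    }
  }
  chain[] <- match(chain, sort(unique(chain)))

  # --- symmetry re-pass --------------------------------------------------
  descOf <- function(root) {
    out <- integer()
    for (x in side) {
      cur <- x
      repeat {
        if (cur == root) { out <- c(out, x); break }
        nxt <- par[[as.character(cur)]]
        if (is.null(nxt) || is.na(nxt) || nxt == ca) break
        cur <- nxt
      }
    }
    out
  }
  for (ev in events) {
    ids <- sort(unique(chain))
    birth <- vapply(ids, function(cc) {
      mem <- as.integer(names(chain)[chain == cc])
      mem[which.min(dist[as.character(mem)])]
    }, integer(1))
    lists <- lapply(ev$kids, function(k) ids[birth %in% descOf(k)])
    u <- sort(unlist(lists))
    if (length(u) < 2L) next
    perm <- setNames(u, u); pos <- 1L
    for (cl in lists) {
      if (!length(cl)) next
      perm[as.character(cl)] <- u[pos:(pos + length(cl) - 1L)]
      pos <- pos + length(cl)
    }
    hit <- chain %in% u
    chain[hit] <- perm[as.character(chain[hit])]
  }

  tb <- data.frame(serial = as.integer(side),
                   distance = unname(dist[as.character(side)]),
                   chain = unname(chain[as.character(side)]),
                   resolvedBy = NA_character_, stringsAsFactors = FALSE)
  tb <- tb[order(tb$distance, tb$chain), ]
  rownames(tb) <- NULL
  new("ChainAssignment", table = tb, audit = "brute-force oracle",
      caSerial = as.integer(ca))
}
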