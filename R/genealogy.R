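# Coalescent genealogies: construction, prior density, simulation, UPGMA
# initialization, Watterson's estimator and Newick interchange.

# epoch durations d_k (k = m..2) from the m-1 internal node times; the
# returned vector is indexed so that element i is d_{i+1}
.intervals_from_times <- function(internalTimes) {
  m <- length(internalTimes) + 1L
  ts <- sort(internalTimes)
  d <- diff(c(0, ts))           # d_m, d_{m-1}, ..., d_2
  rev(d)                        # element i corresponds to k = i + 1
}

#' Construct a genealogy from parent pointers and node times
#'
#' Nodes are indexed 1..2m-1 with the m tips first (at time 0); `parent`
#' is 0 at the root. Epoch durations are derived from the times and stored.
#'
#' @param parent integer parent vector (0 at root).
#' @param times numeric node times (0 at tips), mutation units.
#' @param tipLabels character tip labels.
#' @return a [Genealogy-class] object.
#' @export
genealogy <- function(parent, times, tipLabels) {
  m <- length(tipLabels)
  gen <- new("Genealogy", parent = as.integer(parent), times = as.numeric(times),
             tipLabels = as.character(tipLabels),
             intervals = .intervals_from_times(times[(m + 1L):(2L * m - 1L)]))
  validObject(gen)
  gen
}

#' @describeIn genealogy number of tips
#' @param x a `Genealogy`
#' @export
setMethod("nTips", "Genealogy", function(x) length(x@tipLabels))

#' @describeIn genealogy tip labels
#' @export
setMethod("tipLabels", "Genealogy", function(x) x@tipLabels)

#' @describeIn genealogy node times (tips first, 0 at tips)
#' @export
setMethod("nodeTimes", "Genealogy", function(x) x@times)

#' @describeIn genealogy epoch durations d_k; element i is d_{i+1}
#' @export
setMethod("intervals", "Genealogy", function(x) x@intervals)

#' @describeIn genealogy time of the most recent common ancestor
#' @export
setMethod("rootTime", "Genealogy", function(x) max(x@times))

setMethod("show", "Genealogy", function(object) {
  cat("Genealogy with", nTips(object), "tips; TMRCA =",
      format(rootTime(object), digits = 4), "(mutation units)\n")
})

#' Coalescent log prior density of a genealogy
#'
#' Standard coalescent exponential density over the epoch durations:
#' `log p = sum_{k=2}^{m} [ log(k(k-1)/Theta) - k(k-1) d_k / Theta ]`,
#' which depends on the genealogy only through the intervals d_k.
#'
#' @param gen a [Genealogy-class].
#' @param theta positive scaled mutation rate.
#' @return finite log-density scalar.
#' @export
coalescentLogPrior <- function(gen, theta) {
  stopifnot(is(gen, "Genealogy"))
  if (!is.numeric(theta) || length(theta) != 1 || !is.finite(theta) ||
      theta <= 0)
    stop("theta must be a positive scalar")
  validObject(gen)
  m <- nTips(gen)
  k <- 2:m
  d <- gen@intervals[k - 1L]
  sum(log(k * (k - 1) / theta) - k * (k - 1) * d / theta)
}

#' Simulate a genealogy from the coalescent prior
#'
#' Each epoch duration d_k is exponential with rate k(k-1)/Theta and at
#' every coalescence a uniformly random pair of lineages merges.
#'
#' @param m number of tips (>= 2).
#' @param theta positive scaled mutation rate.
#' @param tipLabels optional tip labels (default "t1".."tm").
#' @return a [Genealogy-class] draw.
#' @export
sampleGenealogy <- function(m, theta, tipLabels = paste0("t", seq_len(m))) {
  if (m < 2) stop("m must be >= 2")
  if (theta <= 0) stop("theta must be positive")
  m <- as.integer(m)
  nnode <- 2L * m - 1L
  parent <- integer(nnode)
  times <- numeric(nnode)
  active <- seq_len(m)
  tcur <- 0
  nxt <- m + 1L
  for (k in m:2) {
    tcur <- tcur + rexp(1, rate = k * (k - 1) / theta)
    pair <- sample(length(active), 2L)
    parent[active[pair]] <- nxt
    times[nxt] <- tcur
    active <- c(active[-pair], nxt)
    nxt <- nxt + 1L
  }
  genealogy(parent, times, tipLabels)
}

# times ordered per topology rank: redraw coalescent-prior intervals but
# keep the relative order of the internal nodes (used by guided init)
.redraw_times <- function(gen, theta) {
  m <- nTips(gen)
  idx <- (m + 1L):(2L * m - 1L)
  d <- rexp(m - 1L, rate = (m:2) * ((m:2) - 1) / theta)
  newTimes <- cumsum(d)                       # sorted coalescence times
  ord <- order(gen@times[idx])                # rank order of internal nodes
  times <- gen@times
  times[idx[ord]] <- newTimes
  genealogy(gen@parent, times, gen@tipLabels)
}

# ---------------------------------------------------------------------------
# phylo interchange (ape)
# ---------------------------------------------------------------------------

#' Convert a genealogy to an ape "phylo" tree
#'
#' Branch lengths are in mutation units (expected substitutions per site).
#'
#' @param gen a [Genealogy-class].
#' @return an object of class `phylo`.
#' @export
asPhylo <- function(gen) {
  stopifnot(is(gen, "Genealogy"))
  m <- nTips(gen)
  nnode <- 2L * m - 1L
  root <- which(gen@parent == 0L)
  # ape numbering: tips 1..m, root m+1, then other internals
  internal <- (m + 1L):nnode
  apeNum <- integer(nnode)
  apeNum[seq_len(m)] <- seq_len(m)
  apeNum[root] <- m + 1L
  rest <- setdiff(internal, root)
  apeNum[rest] <- m + 1L + seq_along(rest)
  child <- which(gen@parent != 0L)
  edge <- cbind(apeNum[gen@parent[child]], apeNum[child])
  edgeLen <- gen@times[gen@parent[child]] - gen@times[child]
  phy <- list(edge = edge, edge.length = edgeLen,
              tip.label = gen@tipLabels, Nnode = m - 1L)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Convert a rooted binary ultrametric "phylo" tree to a genealogy
#'
#' @param phy a rooted binary `phylo` with edge lengths; tip depths must
#'   agree (ultrametric) within `tol` relative to tree height.
#' @param tol relative ultrametricity tolerance.
#' @return a [Genealogy-class].
#' @export
genealogyFromPhylo <- function(phy, tol = 1e-6) {
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.binary(phy) || !ape::is.rooted(phy))
    stop("need a rooted binary tree")
  m <- length(phy$tip.label)
  nnode <- 2L * m - 1L
  depth <- ape::node.depth.edgelength(phy)
  height <- max(depth)
  tipDepth <- depth[seq_len(m)]
  if (height > 0 && max(abs(tipDepth - height)) > tol * height)
    stop("tree is not ultrametric")
  times <- height - depth
  times[seq_len(m)] <- 0
  parent <- integer(nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  # enforce strictly increasing times toward the root (resolve exact ties):
  # process children before parents (deepest nodes first)
  internal <- (m + 1L):nnode
  hops <- integer(nnode)
  for (v in seq_len(nnode)) {
    u <- v
    while (parent[u] != 0L) { hops[v] <- hops[v] + 1L; u <- parent[u] }
  }
  ord <- internal[order(hops[internal], decreasing = TRUE)]
  eps <- max(height, 1) * 1e-9
  for (v in ord) {
    kids <- which(parent == v)
    lo <- max(times[kids])
    if (times[v] <= lo) times[v] <- lo + eps
  }
  genealogy(parent, times, phy$tip.label)
}

#' Write / read genealogies as Newick
#'
#' Branch lengths in mutation units; leaf labels are the sequence ids.
#'
#' @param gen a [Genealogy-class].
#' @param path file path.
#' @return `readNewick` returns a [Genealogy-class]; `writeNewick` its
#'   `path`, invisibly.
#' @export
writeNewick <- function(gen, path) {
  ape::write.tree(asPhylo(gen), file = path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) {
  genealogyFromPhylo(ape::read.tree(path))
}

# ---------------------------------------------------------------------------
# UPGMA initialization
# ---------------------------------------------------------------------------

# Jukes-Cantor-corrected pairwise distances; ambiguous characters are
# dropped pairwise and the raw proportion is capped below 0.75
.jc_distance <- function(aln) {
  chars <- aln@chars
  m <- nrow(chars)
  plain <- matrix(match(chars, c("A", "C", "G", "T")), nrow = m)
  D <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      ok <- !is.na(plain[i, ]) & !is.na(plain[j, ])
      nn <- sum(ok)
      p <- if (nn == 0) 0 else sum(plain[i, ok] != plain[j, ok]) / nn
      p <- min(p, 0.75 - 1e-6)
      D[i, j] <- D[j, i] <- -0.75 * log(1 - 4 * p / 3)
    }
  }
  dimnames(D) <- list(aln@ids, aln@ids)
  D
}

#' UPGMA genealogy from an alignment
#'
#' Average-linkage agglomeration on Jukes-Cantor-corrected pairwise
#' distances; node times are half the cluster heights, which are already
#' in mutation units. Used to initialize the particle genealogies; exact
#' tied merges are resolved deterministically and node times are nudged
#' minimally where ties would violate strict time ordering.
#'
#' @param aln a [SequenceAlignment-class] with at least 2 sequences.
#' @return an ultrametric [Genealogy-class].
#' @export
upgmaTree <- function(aln) {
  stopifnot(is(aln, "SequenceAlignment"))
  if (nSequences(aln) < 2) stop("need at least 2 sequences")
  D <- .jc_distance(aln)
  hc <- hclust(as.dist(D), method = "average")
  # as.phylo already halves merge heights, so node times are (cluster
  # distance)/2, directly in mutation units
  genealogyFromPhylo(ape::as.phylo(hc), tol = 1e-6)
}

# ---------------------------------------------------------------------------
# Watterson's estimator
# ---------------------------------------------------------------------------

#' Watterson's estimator of the per-site scaled mutation rate
#'
#' `S / (l * sum_{i=1}^{m-1} 1/i)` where S counts segregating sites (sites
#' with at least two distinct unambiguous bases). Used mainly to anchor
#' the upper bound of the Theta prior.
#'
#' @param aln a [SequenceAlignment-class].
#' @return nonnegative scalar.
#' @export
wattersonTheta <- function(aln) {
  stopifnot(is(aln, "SequenceAlignment"))
  chars <- aln@chars
  l <- ncol(chars)
  if (l == 0) return(0)
  m <- nrow(chars)
  seg <- apply(chars, 2, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    length(unique(col)) > 1
  })
  S <- sum(seg)
  S / (l * sum(1 / seq_len(m - 1)))
}
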