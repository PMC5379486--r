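# Shared fixtures and independent brute-force oracles.
# Oracles are deliberately written as explicit per-site / per-pair loops,
# independent of the package's vectorized implementations.

# -- brute-force window diversity statistics ------------------------------

# expand one site's dosages into haplotype alleles (het = one of each)
.halleles <- function(dos) {
  out <- integer(0)
  for (x in dos) {
    if (is.na(x)) next
    out <- c(out, if (x == 0L) c(0L, 0L) else if (x == 1L) c(0L, 1L)
             else c(1L, 1L))
  }
  out
}

bruteWindow <- function(d) {
  S <- 0L; pi <- 0; theta <- 0; ns <- integer(0)
  for (i in seq_len(nrow(d))) {
    al <- .halleles(d[i, ])
    n <- length(al)
    if (n < 2L) next
    diffs <- 0L
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
      diffs <- diffs + (al[a] != al[b])
    pi <- pi + diffs / (n * (n - 1L) / 2L)
    seg <- any(al != al[1L])
    if (seg) {
      S <- S + 1L
      a1 <- 0
      for (k in seq_len(n - 1L)) a1 <- a1 + 1 / k
      theta <- theta + 1 / a1
      ns <- c(ns, n)
    }
  }
  D <- NA_real_
  if (S > 0L) {
    n <- as.integer(round(median(ns)))
    if (n >= 4L) {
      a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
      b1 <- (n + 1) / (3 * (n - 1))
      b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
      c1 <- b1 - 1 / a1
      c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
      vd <- (c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1)
      D <- (pi - S / a1) / sqrt(vd)
    }
  }
  list(S = S, pi = pi, theta = theta, D = D)
}

# -- brute-force LD r^2 ---------------------------------------------------

bruteR2 <- function(a, b) {
  nAB <- nAb <- naB <- nab <- 0L
  for (i in seq_along(a)) {
    if (is.na(a[i]) || is.na(b[i]) || a[i] == 1L || b[i] == 1L) next
    x <- a[i] == 2L; y <- b[i] == 2L
    if (x && y) nAB <- nAB + 1L
    else if (x) nAb <- nAb + 1L
    else if (y) naB <- naB + 1L
    else nab <- nab + 1L
  }
  n <- nAB + nAb + naB + nab
  if (n < 2L) return(NA_real_)
  pA <- (nAB + nAb) / n; pB <- (nAB + naB) / n
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(NA_real_)
  (nAB / n - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# -- brute-force origin tracing ------------------------------------------

# exhaustive enumeration over all (block, cultivar) identity tests
bruteTrace <- function(idm, flow, donors, focal, thr = 0.85) {
  upstream <- rev(setdiff(flow, focal))
  out <- list()
  for (b in rownames(idm)) {
    chain <- character(0)
    for (r in upstream) {
      id <- idm[b, r]
      if (!is.na(id) && id >= thr) chain <- c(chain, r) else break
    }
    if (!length(chain)) {
      out[[b]] <- list(traceable = FALSE, origin = NA_character_,
                       count = 0L)
    } else {
      earliest <- chain[length(chain)]
      origin <- earliest
      dn <- donors[earliest]
      if (!is.na(dn) && dn %in% colnames(idm) && !is.na(idm[b, dn]) &&
          idm[b, dn] >= thr)
        origin <- unname(dn)
      out[[b]] <- list(traceable = TRUE, origin = origin,
                       count = length(chain))
    }
  }
  out
}

# -- brute-force one-generation selection step ---------------------------

# explicit per-individual truncation selection + random mating, an
# independent reimplementation of the generation update
bruteStep <- function(A, B, pheno, replaced, mu_eff, directional = TRUE) {
  N <- nrow(A); L <- ncol(A)
  n_off <- round(replaced * N)
  ord <- order(-pheno, seq_len(N))
  surv <- ord[seq_len(N - n_off)]
  nA <- A[surv, , drop = FALSE]; nB <- B[surv, , drop = FALSE]
  for (k in seq_len(n_off)) {
    p1 <- surv[sample.int(length(surv), 1L)]
    p2 <- surv[sample.int(length(surv), 1L)]
    ca <- cb <- integer(L)
    for (l in seq_len(L)) {
      ca[l] <- if (runif(1) < 0.5) A[p1, l] else B[p1, l]
      cb[l] <- if (runif(1) < 0.5) A[p2, l] else B[p2, l]
      for (h in c("a", "b")) {
        v <- if (h == "a") ca[l] else cb[l]
        if (v == 0L && runif(1) < mu_eff[l]) v <- 1L
        else if (!directional && v == 1L && runif(1) < mu_eff[l]) v <- 0L
        if (h == "a") ca[l] <- v else cb[l] <- v
      }
    }
    nA <- rbind(nA, ca); nB <- rbind(nB, cb)
  }
  list(A = nA, B = nB)
}

# -- hand-built pedigree + block genotypes for tracing tests -------------

# 4 receptor generations: F1; R1 = F1 x D1; ...; R4 = R3 x D4 (focal)
handPedigree <- function() {
  nodes <- data.frame(
    name = c("F1", paste0("D", 1:4), paste0("R", 1:4)),
    year = c(1950, 1955, 1960, 1965, 1970, 1955, 1960, 1965, 1970),
    role = c("founder", rep("donor", 4), rep("receptor", 4)))
  edges <- data.frame(
    child = rep(paste0("R", 1:4), each = 2),
    parent = c("F1", "D1", "R1", "D2", "R2", "D3", "R3", "D4"),
    parent_role = rep(c("recurrent", "donor"), 4))
  pedigreeGraph(nodes, edges, focal = "R4")
}

# genotypes with 4 planted 20-marker blocks on one chromosome:
#   block 1: identical across the whole trunk (origin = founder)
#   block 2: introduced by donor D3 (matches D3, R3, R4; not R2/R1)
#   block 3: matches nobody upstream (novel in R4)
#   block 4: broken chain (matches R1/F1 and R4 but not R2/R3)
handBlockGenotypes <- function(ped) {
  lines <- pedigreeNodes(ped)$name
  n_blocks <- 4L
  m <- 20L
  d <- matrix(0L, n_blocks * m, length(lines),
              dimnames = list(NULL, lines))
  hapA <- rep(2L, m); hapB <- rep(0L, m)
  hapC <- rep(c(2L, 0L), m / 2)
  set_block <- function(d, b, line, hap) {
    d[((b - 1) * m + 1):(b * m), line] <- hap; d
  }
  for (ln in lines) d <- set_block(d, 1L, ln, hapA)
  for (ln in c("D3", "R3", "R4")) d <- set_block(d, 2L, ln, hapC)
  d <- set_block(d, 3L, "R4", hapC)
  for (ln in c("F1", "R1", "R4")) d <- set_block(d, 4L, ln, hapC)
  genotypeMatrix(d, chrom = rep("chr1", nrow(d)),
                 pos = seq_len(nrow(d)) * 1000L,
                 lineData = pedigreeNodes(ped))
}

# GRanges of the 4 planted blocks above
handBlockRanges <- function() {
  m <- 20L
  GenomicRanges::GRanges("chr1",
    IRanges::IRanges(((seq_len(4L) - 1L) * m + 1L) * 1000L,
                     (seq_len(4L) * m) * 1000L),
    block_id = paste0("HB", 1:4))
}

# standard mid-size pedigree panel reused across tests (built once)
panelFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ped <- generatePedigree(9, 7, 29, 1948, seed = 7)
      gm <- simulateGenotypes(ped, 1500,
                              c(chr1 = 3e6, chr2 = 3e6, chr3 = 3e6),
                              seed = 2)
      cache <<- list(ped = ped, gm = gm)
    }
    cache
  }
})

# interval-overlap Jaccard between two GRanges
jaccardBp <- function(a, b) {
  a <- GenomicRanges::reduce(a); b <- GenomicRanges::reduce(b)
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(a, b)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(a, b)))
  if (uni == 0) return(NA_real_)
  inter / uni
}

# original + corrected PVE at the planted markers of a QTLSpec
estimateQTLTable <- function(gm, spec, phenotypes) {
  mi <- markerInfo(gm)
  q <- spec@qtls
  q$marker <- rownames(mi)[mapply(function(ch, po)
    which(mi$chrom == ch & mi$pos == po)[1], q$chrom, q$pos)]
  y <- phenotypeMeans(phenotypes, trait = q$trait[1])
  q$original_pve <- vapply(q$marker, function(m)
    originalPVE(gm, y, m), numeric(1))
  q$corrected_pve <- as.numeric(correctedPVE(gm, y, q))
  q
}
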