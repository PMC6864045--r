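## Independent brute-force oracles for guide discovery. Deliberately written
## with plain string operations and a placement-first scan (every 20-mer
## adjacent to an NGG on both genomic strands), so they share no code path
## with the package's window-based finders.

o_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

## splice sites derived directly from exon intervals (1-based plus coords)
o_sites <- function(seqstr, exons, strand) {
  ex <- exons[order(exons$start, decreasing = (strand == "-")), , drop = FALSE]
  n <- nrow(ex)
  if (n < 2L) return(data.frame(kind = character(), g = integer(),
                                canonical = logical(), intron = integer()))
  rows <- lapply(seq_len(n - 1L), function(i) {
    if (strand == "+") {
      don_g <- ex$end[i] + 1L
      acc_g <- ex$start[i + 1L] - 1L
      don_seq <- substr(seqstr, don_g, don_g + 1L)
      acc_seq <- substr(seqstr, acc_g - 1L, acc_g)
    } else {
      don_g <- ex$start[i] - 1L
      acc_g <- ex$end[i + 1L] + 1L
      don_seq <- o_revcomp(substr(seqstr, don_g - 1L, don_g))
      acc_seq <- o_revcomp(substr(seqstr, acc_g, acc_g + 1L))
    }
    data.frame(kind = c("donor", "acceptor"), g = c(don_g, acc_g),
               canonical = c(don_seq == "GT", acc_seq == "AG"), intron = i)
  })
  do.call(rbind, rows)
}

## every antisense protospacer+NGG whose 4-8 window covers a critical C
oracle_splice <- function(seqstr, exons, strand, ws = 4L, we = 8L) {
  sites <- o_sites(seqstr, exons, strand)
  sites <- sites[sites$canonical, , drop = FALSE]
  L <- nchar(seqstr)
  res <- list()
  for (si in seq_len(nrow(sites))) {
    g <- sites$g[si]
    cls <- if (sites$kind[si] == "donor") "splice_donor" else "splice_acceptor"
    if (strand == "+") {
      ## antisense = minus strand; scan every minus placement
      for (a in seq_len(L - 19L)) {
        if (a - 3L < 1L) next
        proto <- o_revcomp(substr(seqstr, a, a + 19L))
        pam <- o_revcomp(substr(seqstr, a - 3L, a - 1L))
        if (!grepl("^[ACGT]GG$", pam)) next
        if (grepl("N", proto, fixed = TRUE)) next
        p <- a + 20L - g
        if (p < ws || p > we) next
        if (substr(proto, p, p) != "C") next
        res[[length(res) + 1L]] <- data.frame(
          class = cls, protospacer = proto, gstrand = "-", proto_lo = a,
          intron = sites$intron[si])
      }
    } else {
      ## antisense = plus strand
      for (b in seq_len(L - 19L)) {
        if (b + 22L > L) next
        proto <- substr(seqstr, b, b + 19L)
        pam <- substr(seqstr, b + 20L, b + 22L)
        if (!grepl("^[ACGT]GG$", pam)) next
        if (grepl("N", proto, fixed = TRUE)) next
        p <- g - b + 1L
        if (p < ws || p > we) next
        if (substr(proto, p, p) != "C") next
        res[[length(res) + 1L]] <- data.frame(
          class = cls, protospacer = proto, gstrand = "+", proto_lo = b,
          intron = sites$intron[si])
      }
    }
  }
  if (length(res)) do.call(rbind, res)
  else data.frame(class = character(), protospacer = character(),
                  gstrand = character(), proto_lo = integer(),
                  intron = integer())
}

## every protospacer+NGG (both strands) with a window C whose edit can make
## an in-frame stop: sense CAA/CAG/CGA (codon position 1) or antisense TGG
## (positions 2/3)
oracle_pmstop <- function(seqstr, cds, strand, ws = 4L, we = 8L) {
  iv <- cds[order(cds$start, decreasing = (strand == "-")), , drop = FALSE]
  pieces <- vapply(seq_len(nrow(iv)), function(i) {
    s <- substr(seqstr, iv$start[i], iv$end[i])
    if (strand == "-") o_revcomp(s) else s
  }, character(1L))
  cds_seq <- paste(pieces, collapse = "")
  n <- nchar(cds_seq)
  stopifnot(n %% 3L == 0L)
  gpos <- unlist(lapply(seq_len(nrow(iv)), function(i) {
    r <- iv$start[i]:iv$end[i]
    if (strand == "-") rev(r) else r
  }))
  codon_seq <- substring(cds_seq, seq(1L, n, 3L), seq(3L, n, 3L))
  ncod <- n %/% 3L
  valid <- if (codon_seq[ncod] %in% c("TAA", "TAG", "TGA"))
    seq_len(ncod - 1L) else seq_len(ncod)
  idx_of <- integer(nchar(seqstr))
  idx_of[gpos] <- seq_len(n)
  L <- nchar(seqstr)
  res <- list()
  for (gstrand in c("+", "-")) {
    for (a in seq_len(L - 19L)) {
      if (gstrand == "+") {
        if (a + 22L > L) next
        proto <- substr(seqstr, a, a + 19L)
        pam <- substr(seqstr, a + 20L, a + 22L)
      } else {
        if (a - 3L < 1L) next
        proto <- o_revcomp(substr(seqstr, a, a + 19L))
        pam <- o_revcomp(substr(seqstr, a - 3L, a - 1L))
      }
      if (!grepl("^[ACGT]GG$", pam)) next
      if (grepl("N", proto, fixed = TRUE)) next
      hits <- integer()
      for (p in ws:we) {
        if (substr(proto, p, p) != "C") next
        gp <- if (gstrand == "+") a + p - 1L else a + 20L - p
        i <- idx_of[gp]
        if (i == 0L) next
        k <- (i - 1L) %/% 3L + 1L
        if (!(k %in% valid)) next
        cp <- (i - 1L) %% 3L + 1L
        cod <- codon_seq[k]
        if (gstrand == strand) {
          if (cp == 1L && cod %in% c("CAA", "CAG", "CGA"))
            hits <- c(hits, k)
        } else {
          if (cp %in% c(2L, 3L) && cod == "TGG") hits <- c(hits, k)
        }
      }
      for (k in unique(hits))
        res[[length(res) + 1L]] <- data.frame(
          class = "pmstop", protospacer = proto, gstrand = gstrand,
          proto_lo = a, codon = k)
    }
  }
  if (length(res)) do.call(rbind, res)
  else data.frame(class = character(), protospacer = character(),
                  gstrand = character(), proto_lo = integer(),
                  codon = integer())
}

## canonical comparison keys
o_key_splice <- function(d) {
  sort(paste(d$class, d$protospacer, d$gstrand, d$proto_lo, sep = "|"))
}
o_key_pmstop <- function(d, codon) {
  sort(paste(d$protospacer, d$gstrand, d$proto_lo, codon, sep = "|"))
}

## pull the raw pieces the oracles need out of package objects
o_inputs <- function(locus) {
  ex <- exonRanges(locus$tm)
  cd <- cdsRanges(locus$tm)
  list(seqstr = as.character(locus$genome[[1L]]),
       exons = data.frame(start = BiocGenerics::start(ex),
                          end = BiocGenerics::end(ex)),
       cds = data.frame(start = BiocGenerics::start(cd),
                        end = BiocGenerics::end(cd)),
       strand = strand(locus$tm))
}
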