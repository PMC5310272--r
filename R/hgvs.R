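# HGVS-style protein notation and effect classification shared by the
# simulator's expected-call channel and the variant caller, so that the two
# sides agree byte-for-byte on every planted edit.
#
# Dialect: three-letter amino-acid codes, "*" for stop, "fs" without an
# extension length ("p.Ala191fs"), "p.Xxx123=" for synonymous changes, and
# upstream records rendered "upstream-9 C->T" / "upstream-1 delA".

STOP_CODONS <- c("TAA", "TAG", "TGA")

aa3 <- function(aa1) {
  code <- Biostrings::AMINO_ACID_CODE
  out <- ifelse(aa1 == "*", "*", unname(code[aa1]))
  if (anyNA(out)) stop("unknown amino acid code: ", paste(aa1[is.na(out)], collapse = ","))
  out
}

codon2aa <- function(codon) {
  gc11 <- Biostrings::getGeneticCode("11")
  aa <- unname(gc11[toupper(codon)])
  if (anyNA(aa)) stop("not a codon: ", paste(codon[is.na(aa)], collapse = ","))
  aa
}

translateStr <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n < 3L) return("")
  codons <- substring(nt, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  paste(codon2aa(codons), collapse = "")
}

# ---- indel left-normalization ----------------------------------------------

# Deletion of S[p .. p+L-1]: shift left while the base preceding the deletion
# equals the last deleted base (identical resulting sequence).
normalizeDeletion <- function(S, p, L) {
  s <- strsplit(S, "")[[1]]
  while (p > 1L && s[p - 1L] == s[p + L - 1L]) p <- p - 1L
  list(pos = p, ref = substr(S, p, p + L - 1L))
}

# Insertion of T before S[g]: shift left while T's last base equals S[g-1]
# (rotating T right).
normalizeInsertion <- function(S, g, T) {
  s <- strsplit(S, "")[[1]]
  t <- strsplit(T, "")[[1]]
  L <- length(t)
  while (g > 1L && t[L] == s[g - 1L]) {
    t <- c(s[g - 1L], t[-L])
    g <- g - 1L
  }
  list(pos = g, alt = paste(t, collapse = ""))
}

applyEvent <- function(S, ev) {
  if (ev$type == "sub") {
    substr(S, ev$pos, ev$pos) <- ev$alt
    S
  } else if (ev$type == "del") {
    paste0(substr(S, 1L, ev$pos - 1L), substr(S, ev$pos + nchar(ev$ref), nchar(S)))
  } else if (ev$type == "ins") {
    paste0(substr(S, 1L, ev$pos - 1L), ev$alt, substr(S, ev$pos, nchar(S)))
  } else stop("unknown event type ", ev$type)
}

# ---- protein-level diff for in-frame events --------------------------------

proteinDiff <- function(pa, pd) {
  a <- strsplit(pa, "")[[1]]
  d <- strsplit(pd, "")[[1]]
  na <- length(a); nd <- length(d)
  lcp <- 0L
  while (lcp < min(na, nd) && a[lcp + 1L] == d[lcp + 1L]) lcp <- lcp + 1L
  lcs <- 0L
  while (lcs < min(na, nd) - lcp && a[na - lcs] == d[nd - lcs]) lcs <- lcs + 1L
  list(
    lcp = lcp,
    del = if (na - lcs > lcp) a[(lcp + 1L):(na - lcs)] else character(),
    ins = if (nd - lcs > lcp) d[(lcp + 1L):(nd - lcs)] else character()
  )
}

formatSub <- function(refAA, pos, altAA) {
  if (refAA == altAA) return(sprintf("p.%s%d=", aa3(refAA), pos))
  if (altAA == "*") return(sprintf("p.%s%d*", aa3(refAA), pos))
  if (refAA == "*") return(sprintf("p.Ter%d%s", pos, aa3(altAA)))
  sprintf("p.%s%d%s", aa3(refAA), pos, aa3(altAA))
}

# Classify one or more substitutions falling in the same codon (annotated
# jointly: the consequence is that of the fully edited codon).
classifyCodonSubs <- function(ancSeq, positions, alts) {
  ci <- (positions[1L] - 1L) %/% 3L + 1L
  stopifnot(all((positions - 1L) %/% 3L + 1L == ci))
  anc_codon <- substr(ancSeq, 3L * ci - 2L, 3L * ci)
  der_codon <- anc_codon
  for (i in seq_along(positions)) {
    off <- positions[i] - (3L * ci - 2L) + 1L
    substr(der_codon, off, off) <- alts[i]
  }
  refAA <- codon2aa(anc_codon)
  altAA <- codon2aa(der_codon)
  effect <- if (refAA == altAA) "synonymous"
    else if (altAA == "*") "stop_gained"
    else if (refAA == "*") "stop_lost"
    else "missense"
  refs <- substring(anc_codon, positions - (3L * ci - 2L) + 1L,
                    positions - (3L * ci - 2L) + 1L)
  list(effect = effect,
       protein_notation = formatSub(refAA, ci, altAA),
       nt_change = paste(sprintf("c.%d%s>%s", positions, refs, alts),
                         collapse = ";"))
}

# Classify a single CDS event (already in ancestor gene-local coordinates,
# coding strand).  Indels are left-normalized here, so callers may pass the
# raw planted/aligned position.
classifyCDSEvent <- function(ancSeq, ev) {
  if (ev$type == "sub") {
    return(classifyCodonSubs(ancSeq, ev$pos, ev$alt))
  }
  if (ev$type == "del") {
    L <- nchar(ev$ref)
    nrm <- normalizeDeletion(ancSeq, ev$pos, L)
    p <- nrm$pos
    nt_change <- if (L == 1L) sprintf("c.%ddel%s", p, nrm$ref)
      else sprintf("c.%d_%ddel%s", p, p + L - 1L, nrm$ref)
    if (L %% 3L != 0L) {
      ci <- (p - 1L) %/% 3L + 1L
      refAA <- codon2aa(substr(ancSeq, 3L * ci - 2L, 3L * ci))
      return(list(effect = "frameshift",
                  protein_notation = sprintf("p.%s%dfs", aa3(refAA), ci),
                  nt_change = nt_change))
    }
    der <- applyEvent(ancSeq, list(type = "del", pos = p, ref = nrm$ref))
    return(c(inframeConsequence(ancSeq, der), list(nt_change = nt_change)))
  }
  if (ev$type == "ins") {
    nrm <- normalizeInsertion(ancSeq, ev$pos, ev$alt)
    p <- nrm$pos
    L <- nchar(nrm$alt)
    nt_change <- sprintf("c.%d_%dins%s", p - 1L, p, nrm$alt)
    if (L %% 3L != 0L) {
      ci <- (p - 1L) %/% 3L + 1L
      ci <- min(ci, nchar(ancSeq) %/% 3L)
      refAA <- codon2aa(substr(ancSeq, 3L * ci - 2L, 3L * ci))
      return(list(effect = "frameshift",
                  protein_notation = sprintf("p.%s%dfs", aa3(refAA), ci),
                  nt_change = nt_change))
    }
    der <- applyEvent(ancSeq, list(type = "ins", pos = p, alt = nrm$alt))
    return(c(inframeConsequence(ancSeq, der), list(nt_change = nt_change)))
  }
  stop("unknown event type: ", ev$type)
}

# Consequence of an in-frame change: compare ancestor and single-event
# derived translations by longest common prefix/suffix.
inframeConsequence <- function(ancSeq, derSeq) {
  pa <- translateStr(ancSeq)
  pd <- translateStr(derSeq)
  dif <- proteinDiff(pa, pd)
  a <- strsplit(pa, "")[[1]]
  if (length(dif$del) == 0L && length(dif$ins) == 0L) {
    # nucleotide-level indel invisible at the protein level
    return(list(effect = "synonymous",
                protein_notation = sprintf("p.%s%d=", aa3(a[max(dif$lcp, 1L)]),
                                           max(dif$lcp, 1L))))
  }
  stop_gained <- grepl("*", paste(dif$ins, collapse = ""), fixed = TRUE)
  if (length(dif$ins) == 0L) {
    i <- dif$lcp + 1L
    j <- dif$lcp + length(dif$del)
    notation <- if (i == j) sprintf("p.%s%ddel", aa3(a[i]), i)
      else sprintf("p.%s%d_%s%ddel", aa3(a[i]), i, aa3(a[j]), j)
    return(list(effect = "inframe_deletion", protein_notation = notation))
  }
  if (length(dif$del) == 0L) {
    i <- dif$lcp
    insres <- paste(aa3(dif$ins), collapse = "")
    notation <- if (i >= 1L && i < length(a))
      sprintf("p.%s%d_%s%dins%s", aa3(a[i]), i, aa3(a[i + 1L]), i + 1L, insres)
      else sprintf("p.%dins%s", i + 1L, insres)
    return(list(effect = "inframe_insertion", protein_notation = notation))
  }
  # delins (non-codon-aligned in-frame change)
  i <- dif$lcp + 1L
  j <- dif$lcp + length(dif$del)
  insres <- paste(aa3(dif$ins), collapse = "")
  notation <- if (i == j) sprintf("p.%s%ddelins%s", aa3(a[i]), i, insres)
    else sprintf("p.%s%d_%s%ddelins%s", aa3(a[i]), i, aa3(a[j]), j, insres)
  effect <- if (stop_gained) "stop_gained"
    else if (length(dif$ins) < length(dif$del)) "inframe_deletion"
    else if (length(dif$ins) > length(dif$del)) "inframe_insertion"
    else "missense"
  list(effect = effect, protein_notation = notation)
}

# Classify an event in the upstream flank (flank coordinates 1..window, with
# flank position `window` sitting at offset -1 from the start codon).
classifyUpstreamEvent <- function(flank, ev, window = nchar(flank)) {
  if (ev$type == "sub") {
    offset <- ev$pos - window - 1L
    return(list(effect = "upstream", upstream_offset = offset,
                protein_notation = sprintf("upstream%d %s->%s", offset,
                                           ev$ref, ev$alt),
                nt_change = sprintf("upstream%d %s->%s", offset, ev$ref, ev$alt)))
  }
  if (ev$type == "del") {
    nrm <- normalizeDeletion(flank, ev$pos, nchar(ev$ref))
    offset <- nrm$pos - window - 1L
    lab <- sprintf("upstream%d del%s", offset, nrm$ref)
    return(list(effect = "upstream", upstream_offset = offset,
                protein_notation = lab, nt_change = lab))
  }
  if (ev$type == "ins") {
    nrm <- normalizeInsertion(flank, ev$pos, ev$alt)
    offset <- nrm$pos - window - 1L
    lab <- sprintf("upstream%d ins%s", offset, nrm$alt)
    return(list(effect = "upstream", upstream_offset = offset,
                protein_notation = lab, nt_change = lab))
  }
  stop("unknown event type: ", ev$type)
}
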