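# Independent oracles used across the suite. These deliberately avoid the
# package's own normalization/interval code paths: edits are applied by
# plain string surgery and equivalences are found by exhaustive
# enumeration, so they can arbitrate what the fast implementations return.

# apply a (pos, ref, alt) edit to a contig string; 1-based pos
apply_edit <- function(s, pos, ref, alt) {
  stopifnot(substr(s, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(s, 1L, pos - 1L), alt, substr(s, pos + nchar(ref), nchar(s)))
}

# every (pos, ref, alt) representation whose application to `s` yields
# `edited`, by brute force over all anchor/span combinations
enumerate_equivalents <- function(s, edited) {
  L <- nchar(s); E <- nchar(edited)
  out <- list()
  for (p in seq_len(L)) {
    if (substr(s, 1L, p - 1L) != substr(edited, 1L, p - 1L)) break
    for (r in seq_len(L - p + 1L)) {
      alen <- E - (L - r)
      if (alen < 1L || p + alen - 1L > E) next
      if (substr(s, p + r, L) != substr(edited, p + alen, E)) next
      refa <- substr(s, p, p + r - 1L)
      alta <- substr(edited, p, p + alen - 1L)
      if (refa == alta) next
      out[[length(out) + 1L]] <-
        data.frame(pos = p, ref = refa, alt = alta, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# leftmost parsimonious representation among the enumerated equivalents:
# parsimony (minimal total allele span) first, then the smallest position
# among the minimal-span candidates
leftmost_parsimonious <- function(equivs) {
  span <- nchar(equivs$ref) + nchar(equivs$alt)
  cand <- equivs[span == min(span), , drop = FALSE]
  cand <- cand[cand$pos == min(cand$pos), , drop = FALSE]
  stopifnot(nrow(cand) == 1L)
  cand
}

random_contig <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# a random biallelic edit on `s`, in a possibly denormalized
# representation (padded with shared flanking bases, MNP blocks, or
# right-shifted indels), plus the edited sequence it produces
random_edit_case <- function(s) {
  L <- nchar(s)
  type <- sample(c("snv", "ins", "del", "mnp"), 1L)
  if (type == "snv") {
    p <- sample(L, 1L)
    r <- substr(s, p, p)
    a <- sample(setdiff(c("A", "C", "G", "T"), r), 1L)
  } else if (type == "ins") {
    p <- sample(L, 1L)
    r <- substr(s, p, p)
    a <- paste0(r, random_contig(sample(3L, 1L)))
  } else if (type == "del") {
    dl <- sample(3L, 1L)
    p <- sample(L - dl, 1L)
    r <- substr(s, p, p + dl)
    a <- substr(s, p, p)
  } else {
    w <- sample(2:3, 1L)
    p <- sample(L - w + 1L, 1L)
    r <- substr(s, p, p + w - 1L)
    a <- random_contig(w)
    if (a == r) {
      substr(a, 1L, 1L) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(r, 1L, 1L)), 1L)
    }
  }
  # optionally pad with shared flanking reference bases (denormalize)
  pad_l <- sample(0:2, 1L)
  pad_r <- sample(0:2, 1L)
  while (pad_l > 0L && p - pad_l < 1L) pad_l <- pad_l - 1L
  while (pad_r > 0L && p + nchar(r) - 1L + pad_r > L) pad_r <- pad_r - 1L
  if (pad_l > 0L) {
    pre <- substr(s, p - pad_l, p - 1L)
    r <- paste0(pre, r); a <- paste0(pre, a); p <- p - pad_l
  }
  if (pad_r > 0L) {
    post <- substr(s, p + nchar(r), p + nchar(r) + pad_r - 1L)
    r <- paste0(r, post); a <- paste0(a, post)
  }
  list(pos = p, ref = r, alt = a, edited = apply_edit(s, p, r, a))
}

# brute-force per-base membership: which calls overlap >= 1 panel base
brute_force_in_panel <- function(calls, panel) {
  vapply(seq_len(nrow(calls)), function(i) {
    span <- seq.int(calls$pos[i] - 1L, calls$pos[i] - 2L + nchar(calls$ref[i]))
    any(vapply(span, function(p) {
      any(panel$contig == calls$contig[i] & panel$start <= p & p < panel$end)
    }, logical(1)))
  }, logical(1))
}

# brute-force percent of panel bases at depth >= threshold
brute_force_pct_at_depth <- function(track, panel, threshold) {
  n_ok <- 0L; n_tot <- 0L
  for (i in seq_len(nrow(panel))) {
    for (p in seq.int(panel$start[i], panel$end[i] - 1L)) {
      n_tot <- n_tot + 1L
      hit <- track$contig == panel$contig[i] & track$pos == p
      d <- if (any(hit)) track$depth[which(hit)[1]] else 0L
      if (d >= threshold) n_ok <- n_ok + 1L
    }
  }
  100 * n_ok / n_tot
}
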