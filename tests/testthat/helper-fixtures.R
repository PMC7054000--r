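# Shared in-code fixtures for the test suite. Everything is generated
# programmatically; no data files.

# minimal trajectory-shaped object with hand-chosen bridges, for driving the
# contact-map modes with controlled inputs
fake_trajectory <- function(left, right, n_monomers) {
  left <- rbind(left); right <- rbind(right)
  storage.mode(left) <- storage.mode(right) <- "integer"
  structure(list(left = left, right = right,
                 lhalt = matrix(FALSE, nrow(left), ncol(left)),
                 rhalt = matrix(FALSE, nrow(left), ncol(left)),
                 replicate = rep(1L, nrow(left)),
                 step = seq_len(nrow(left)),
                 lifetimes = numeric(0), halt_durations = numeric(0),
                 counts = c(loads = 0L, dissociations = 0L, halts = 0L,
                            resumes = 0L),
                 params = list(n_monomers = as.integer(n_monomers)),
                 ctcf = NULL),
            class = "extrusion_trajectory")
}

# a CTCF track with no sites (free extrusion)
empty_ctcf <- function(n_monomers) {
  ctcf_track(n_monomers, integer(), character(), numeric())
}

# two-block TAD toy map: blocks [1, split) and [split, n], weight w
two_block_map <- function(n = 100, split = 51, w = 2, decay = 1) {
  make_toy_contact_map(toy_map_spec(n, bin_size = 10000, tad_blocks =
    data.frame(start_bin = c(1, split), end_bin = c(split, n + 1),
               intra_weight = c(w, w)), decay_exponent = decay))
}

# random interval set on [0, span) as a data frame
random_intervals <- function(n, span = 10000, max_len = 300, chrom = "chr1") {
  start <- floor(runif(n, 0, span - max_len))
  data.frame(chrom = chrom, start = start,
             end = start + ceiling(runif(n, 1, max_len)))
}

# O(n^2) reference for interval_union_overlap: merge transitively
# overlapping intervals by sweeping, then test set membership pairwise
brute_union_overlap <- function(sets) {
  all <- do.call(rbind, lapply(names(sets), function(nm) {
    x <- as.data.frame(sets[[nm]]); x$set <- nm; x
  }))
  out <- NULL
  for (ch in sort(unique(all$chrom))) {
    a <- all[all$chrom == ch, ]
    a <- a[order(a$start, a$end), ]
    cur_s <- a$start[1]; cur_e <- a$end[1]
    flush <- function(s, e) {
      memb <- sort(unique(a$set[a$start < e & a$end > s]))
      data.frame(chrom = ch, start = s, end = e,
                 membership = paste(memb[order(match(memb, names(sets)))],
                                    collapse = ","),
                 n_sets = length(memb))
    }
    if (nrow(a) > 1) {
      for (i in 2:nrow(a)) {
        if (a$start[i] < cur_e) cur_e <- max(cur_e, a$end[i])
        else { out <- rbind(out, flush(cur_s, cur_e)); cur_s <- a$start[i]; cur_e <- a$end[i] }
      }
    }
    out <- rbind(out, flush(cur_s, cur_e))
  }
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}
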