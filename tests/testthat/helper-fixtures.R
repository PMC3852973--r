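# Shared fixtures and independent brute-force oracles.

app_seqs <- function() read_fasta(domainmapr_example("app695.fasta"))

app_constructs <- function() {
  read_constructs(domainmapr_example("constructs.tsv"), app_seqs())
}

app_observations <- function() {
  readr::read_tsv(domainmapr_example("observations_table1.tsv"),
                  show_col_types = FALSE)
}

toy_construct <- function(residues, id = "toy", ref_start = 1,
                          ref_end = nchar(residues), init_met = FALSE,
                          ctag = "", parent = residues) {
  seqs <- tibble::tibble(id = "parent", residues = parent,
                         description = "toy parent")
  build_constructs(
    tibble::tibble(id = id, parent = "parent", ref_start = ref_start,
                   ref_end = ref_end, init_met = init_met, ctag = ctag),
    seqs
  )
}

random_chain <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}

# position-by-position scan, written independently of cleavage_sites()
oracle_sites <- function(chain, spec, include_slow = FALSE) {
  chars <- strsplit(chain, "")[[1]]
  out <- data.frame(p1_pos = integer(), rate_class = character())
  for (i in seq_len(length(chars) - 1)) {
    p1 <- chars[i]
    p1p <- chars[i + 1]
    if (p1p %in% spec$p1prime_block) next
    if (length(spec$p1prime_target) > 0) {
      if (p1p %in% spec$p1prime_target) {
        out <- rbind(out, data.frame(p1_pos = i, rate_class = "fast"))
      }
      next
    }
    cls <- NULL
    if (p1 %in% spec$p1_fast) {
      cls <- if (p1p %in% spec$p1prime_slow) "slow" else "fast"
    } else if (p1 %in% spec$p1_slow) {
      cls <- "slow"
    }
    if (!is.null(cls) && (include_slow || cls == "fast")) {
      out <- rbind(out, data.frame(p1_pos = i, rate_class = cls))
    }
  }
  out
}

# exhaustive candidate enumeration + ranking for fragment inference
oracle_infer <- function(construct, protease, read, observed_mass,
                         tolerance = 0.01) {
  chain <- construct$chain
  spec <- domainmapr::protease_specs()[[protease]]
  starts <- c()
  for (i in seq_len(nchar(chain) - nchar(read) + 1)) {
    if (substr(chain, i, i + nchar(read) - 1) == read) starts <- c(starts, i)
  }
  parent_hi <- construct$n_met + construct$parent_len
  legal_ends <- oracle_sites(chain, spec)$p1_pos
  legal_ends <- legal_ends[legal_ends <= parent_hi]
  rows <- data.frame()
  for (s in starts) {
    ends <- c(legal_ends[legal_ends >= s + nchar(read) - 1],
              nchar(chain))
    for (e in unique(ends)) {
      th <- peptide_mass(substr(chain, s, e))
      rows <- rbind(rows, data.frame(local_start = s, local_end = e,
                                     theoretical_mass = th))
    }
  }
  rows$delta <- observed_mass - rows$theoretical_mass
  over <- rows$theoretical_mass > observed_mass * (1 + tolerance)
  rows <- rows[order(over, abs(rows$delta), rows$local_end), ]
  rows$rank <- seq_len(nrow(rows))
  rows
}

# brute-force interval union via position marking
oracle_merge <- function(starts, ends) {
  if (length(starts) == 0) {
    return(data.frame(ref_start = integer(), ref_end = integer()))
  }
  hi <- max(ends) + 2L
  covered <- rep(FALSE, hi)
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  # adjacency counts as merged: close single-position gaps between intervals
  r <- rle(covered)
  pos <- cumsum(r$lengths)
  out <- data.frame(ref_start = integer(), ref_end = integer())
  idx <- which(r$values)
  for (k in idx) {
    s <- pos[k] - r$lengths[k] + 1L
    e <- pos[k]
    out <- rbind(out, data.frame(ref_start = s, ref_end = e))
  }
  # merge adjacent intervals (gap of zero residues between e and s=e+1 is
  # already continuous; adjacency means next start == prev end + 1 after
  # run-length encoding, which rle cannot produce, so handle touching runs)
  if (nrow(out) > 1) {
    keep <- list(out[1, ])
    for (i in 2:nrow(out)) {
      prev <- keep[[length(keep)]]
      if (out$ref_start[i] <= prev$ref_end + 1L) {
        prev$ref_end <- max(prev$ref_end, out$ref_end[i])
        keep[[length(keep)]] <- prev
      } else {
        keep[[length(keep) + 1]] <- out[i, ]
      }
    }
    out <- do.call(rbind, keep)
  }
  out
}
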