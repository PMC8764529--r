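# Brute-force oracles kept deliberately independent of the package internals:
# plain double loops and naive recursions, no shared geometry code.

euclid <- function(p, q) sqrt(sum((p - q)^2))

atom_xyz <- function(atoms, i) c(atoms$x[i], atoms$y[i], atoms$z[i])

# all ligand-N/O to environment-N/O pairs within [lo, hi], as a sorted key set
oracle_hbond_pairs <- function(model, lig_keep, lo, hi) {
  a <- model$atoms
  lig <- a[lig_keep & a$element %in% c("N", "O"), , drop = FALSE]
  env <- a[!lig_keep & a$element %in% c("N", "O"), , drop = FALSE]
  keys <- character()
  for (i in seq_len(nrow(lig))) {
    for (j in seq_len(nrow(env))) {
      d <- euclid(atom_xyz(lig, i), atom_xyz(env, j))
      if (d >= lo && d <= hi) {
        keys <- c(keys, paste(lig$name[i], env$chain[j], env$res_num[j],
                              env$name[j], round(d, 9), sep = "|"))
      }
    }
  }
  sort(keys)
}

# direct protein-ligand contacts within cutoff, per chain, as sorted keys
oracle_direct_contacts <- function(model, lig_name, cutoff) {
  a <- model$atoms
  water <- c("HOH", "WAT", "H2O", "DOD")
  metals <- c("MG", "MN", "ZN", "CA", "NA", "FE")
  keys <- character()
  for (ch in sort(unique(a$chain[a$res_name == lig_name]))) {
    lig <- a[a$res_name == lig_name & a$chain == ch, , drop = FALSE]
    pr <- a[a$chain == ch & !a$is_hetero & !(a$res_name %in% water) &
              !(a$element %in% metals), , drop = FALSE]
    for (i in seq_len(nrow(pr))) {
      for (j in seq_len(nrow(lig))) {
        d <- euclid(atom_xyz(pr, i), atom_xyz(lig, j))
        if (d <= cutoff) {
          keys <- c(keys, paste(ch, pr$res_num[i], pr$name[i], lig$name[j],
                                round(d, 9), sep = "|"))
        }
      }
    }
  }
  sort(keys)
}

oracle_metal_shell <- function(model, element, cutoff) {
  a <- model$atoms
  m <- a[a$element == element, , drop = FALSE]
  keys <- character()
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(nrow(a))) {
      if (!(a$element[j] %in% c("N", "O"))) next
      d <- euclid(atom_xyz(m, i), atom_xyz(a, j))
      if (d <= cutoff) {
        keys <- c(keys, paste(m$serial[i], a$chain[j], a$res_num[j], a$name[j],
                              round(d, 9), sep = "|"))
      }
    }
  }
  sort(keys)
}

# naive memoized Needleman-Wunsch score
oracle_nw_score <- function(a, b, match, mismatch, gap) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    if (i == 0) return(gap * j)
    if (j == 0) return(gap * i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- max(rec(i - 1, j - 1) + (if (va[i] == vb[j]) match else mismatch),
             rec(i - 1, j) + gap,
             rec(i, j - 1) + gap)
    memo[[key]] <- v
    v
  }
  rec(length(va), length(vb))
}

# exhaustive enumeration of all global alignments (tiny inputs only)
oracle_nw_exhaustive <- function(a, b, match, mismatch, gap) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, sc) {
    if (i > length(va) && j > length(vb)) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i <= length(va) && j <= length(vb)) {
      rec(i + 1, j + 1, sc + (if (va[i] == vb[j]) match else mismatch))
    }
    if (i <= length(va)) rec(i + 1, j, sc + gap)
    if (j <= length(vb)) rec(i, j + 1, sc + gap)
  }
  rec(1, 1, 0)
  best
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rigid_rmsd <- function(ref, mov, R, t) {
  moved <- mov %*% t(R) + matrix(t, nrow(mov), 3, byrow = TRUE)
  sqrt(mean(rowSums((moved - ref)^2)))
}
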