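# Independent reference implementations used to validate the production
# algorithms. Deliberately naive: enumeration and scalar dynamic programming,
# sharing no code with the package internals.

# Smallest string among all rotations of s and of its reverse complement,
# by explicit enumeration.
oracle_canonical <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ch <- strsplit(s, "")[[1]]
  rc <- paste(rev(unname(comp[ch])), collapse = "")
  rots <- function(x) {
    n <- nchar(x)
    vapply(seq_len(n) - 1L, function(k) {
      paste0(substring(x, k + 1L, n), substring(x, 1L, k))
    }, character(1))
  }
  min(c(rots(s), rots(rc)))
}

# Largest k in [min_k, floor(frac * L)] with prefix == suffix, by ascending
# character-wise comparison of every k.
oracle_terminal_overlap <- function(seq, min_k, frac = 0.5) {
  L <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  best <- NA_integer_
  kmax <- min(floor(frac * L), L - 1L)
  if (L < 2L * min_k || kmax < min_k) return(best)
  for (k in min_k:kmax) {
    if (all(ch[1:k] == ch[(L - k + 1L):L])) best <- k
  }
  best
}

# Exhaustive gapless best-diagonal alignment of read vs window; best by
# match count, then aligned columns, then smallest window start.
oracle_window_align <- function(read, window) {
  rc <- strsplit(read, "")[[1]]
  wc <- strsplit(window, "")[[1]]
  lr <- length(rc); lw <- length(wc)
  best <- NULL
  for (d in (-(lw - 1L)):(lr - 1L)) {
    ws <- max(0L, -d); we <- min(lw, lr - d)
    if (we <= ws) next
    matches <- 0L
    for (j in (ws + 1L):we) if (wc[j] == rc[d + j]) matches <- matches + 1L
    cand <- list(window_start = ws, window_end = we, columns = we - ws,
                 matches = matches)
    if (is.null(best) || cand$matches > best$matches ||
        (cand$matches == best$matches && cand$columns > best$columns) ||
        (cand$matches == best$matches && cand$columns == best$columns &&
         cand$window_start < best$window_start)) {
      best <- cand
    }
  }
  best
}

# As oracle_window_align but with vectorised per-diagonal match counting on
# character vectors, for the large-scale agreement checks.
oracle_window_align_fast <- function(read, window) {
  rc <- strsplit(read, "")[[1]]
  wc <- strsplit(window, "")[[1]]
  lr <- length(rc); lw <- length(wc)
  best <- NULL
  for (d in (-(lw - 1L)):(lr - 1L)) {
    ws <- max(0L, -d); we <- min(lw, lr - d)
    if (we <= ws) next
    matches <- sum(wc[(ws + 1L):we] == rc[(d + ws + 1L):(d + we)])
    cand <- list(window_start = ws, window_end = we, columns = we - ws,
                 matches = matches)
    if (is.null(best) || cand$matches > best$matches ||
        (cand$matches == best$matches && cand$columns > best$columns) ||
        (cand$matches == best$matches && cand$columns == best$columns &&
         cand$window_start < best$window_start)) {
      best <- cand
    }
  }
  best
}

# Scalar DP oracle for primer binding feasibility on the forward strand of a
# template. For every end column it computes (a) the unconstrained minimum
# edit distance of a full semi-global primer alignment and (b) the set of
# (mm, ins, del) compositions achievable under the per-category caps, as a
# bitmask over the 8 cap states. A binding exists at an end iff some capped
# composition attains the minimum distance there.
# Returns list(any_hit, best_total): best_total is the smallest total edit
# count over accepted ends (NA when no hit).
oracle_primer_binding <- function(primer, template, max_mm = 1L, max_ins = 1L,
                                  max_del = 1L) {
  p <- utf8ToInt(primer); t <- utf8ToInt(template)
  m <- length(p); n <- length(t)
  if (m > n) return(list(any_hit = FALSE, best_total = NA_integer_))
  stopifnot(max_mm == 1L, max_ins == 1L, max_del == 1L)  # oracle fixed at 1,1,1
  sid <- function(mm, ins, del) mm + 2L * ins + 4L * del       # 0..7
  bit <- function(s) bitwShiftL(1L, s)
  # lookup tables over 8-bit masks
  t_mm <- t_ins <- t_del <- integer(256)
  for (mask in 0:255) {
    acc_m <- acc_i <- acc_d <- 0L
    for (s in 0:7) {
      if (!bitwAnd(mask, bit(s))) next
      mm <- bitwAnd(s, 1L); ins <- bitwAnd(bitwShiftR(s, 1L), 1L)
      del <- bitwAnd(bitwShiftR(s, 2L), 1L)
      if (mm == 0L) acc_m <- bitwOr(acc_m, bit(sid(1L, ins, del)))
      if (ins == 0L) acc_i <- bitwOr(acc_i, bit(sid(mm, 1L, del)))
      if (del == 0L) acc_d <- bitwOr(acc_d, bit(sid(mm, ins, 1L)))
    }
    t_mm[mask + 1L] <- acc_m; t_ins[mask + 1L] <- acc_i; t_del[mask + 1L] <- acc_d
  }
  state_total <- vapply(0:7, function(s) {
    bitwAnd(s, 1L) + bitwAnd(bitwShiftR(s, 1L), 1L) + bitwAnd(bitwShiftR(s, 2L), 1L)
  }, integer(1))

  mask_prev <- rep(1L, n + 1L)           # state (0,0,0) reachable, free start
  dist_prev <- rep(0L, n + 1L)
  BIG <- 10000L
  for (i in seq_len(m)) {
    mask_cur <- integer(n + 1L)
    dist_cur <- integer(n + 1L)
    for (j in 0:n) {
      jj <- j + 1L
      mk <- 0L; dd <- BIG
      if (j > 0L) {
        same <- t[j] == p[i]
        if (same) mk <- mask_prev[jj - 1L]
        mk <- bitwOr(mk, t_mm[mask_prev[jj - 1L] + 1L])
        dd <- min(dd, dist_prev[jj - 1L] + if (same) 0L else 1L)
      }
      mk <- bitwOr(mk, t_del[mask_prev[jj] + 1L])
      dd <- min(dd, dist_prev[jj] + 1L)
      if (j > 0L) {
        mk <- bitwOr(mk, t_ins[mask_cur[jj - 1L] + 1L])
        dd <- min(dd, dist_cur[jj - 1L] + 1L)
      }
      mask_cur[jj] <- mk
      dist_cur[jj] <- dd
    }
    mask_prev <- mask_cur
    dist_prev <- dist_cur
  }
  best_total <- NA_integer_
  any_hit <- FALSE
  for (j in 0:n) {
    mk <- mask_prev[j + 1L]
    if (mk == 0L) next
    totals <- state_total[which(bitwAnd(mk, bitwShiftL(1L, 0:7)) > 0L)]
    if (any(totals == dist_prev[j + 1L])) {
      any_hit <- TRUE
      best_total <- min(best_total, dist_prev[j + 1L], na.rm = TRUE)
    }
  }
  list(any_hit = any_hit, best_total = best_total)
}

# Substitute the base at 1-based position p with a different one.
mutate_base <- function(s, p) {
  b <- substr(s, p, p)
  repl <- setdiff(c("A", "C", "G", "T"), b)[1]
  paste0(substr(s, 1, p - 1L), repl, substr(s, p + 1L, nchar(s)))
}

# Delete (type = "del") or insert (type = "ins") one base at position p.
indel_base <- function(s, p, type = c("del", "ins"), base = "A") {
  type <- match.arg(type)
  if (type == "del") {
    paste0(substr(s, 1, p - 1L), substr(s, p + 1L, nchar(s)))
  } else {
    paste0(substr(s, 1, p), base, substr(s, p + 1L, nchar(s)))
  }
}

# Random contig with a planted terminal duplication of dup_len (0 = none).
planted_overlap_contig <- function(core_len, dup_len, gc = 0.45) {
  core <- paste(sample(c("A", "C", "G", "T"), core_len, replace = TRUE,
                       prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
                collapse = "")
  if (dup_len > 0L) paste0(core, substr(core, 1L, dup_len)) else core
}
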