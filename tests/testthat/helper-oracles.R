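# Independent brute-force oracles, deliberately written without reusing the
# package's DP/C++ code paths: plain R recursion over pair lists.

CANONICAL <- c("AU", "UA", "GC", "CG", "GU", "UG")

oracle_can_pair <- function(chars, i, j) {
  paste0(chars[i], chars[j]) %in% CANONICAL
}

# all valid structures of a sequence, as a list of pair matrices
oracle_enumerate <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < 4L) return(list(matrix(integer(0), ncol = 2L)))
    key <- paste0(i, "_", j)
    hit <- get0(key, envir = memo, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    out <- rec(i + 1L, j)  # i unpaired
    for (k in (i + 4L):j) {
      if (!oracle_can_pair(chars, i, k)) next
      inner <- rec(i + 1L, k - 1L)
      rest <- if (k + 1L <= j) rec(k + 1L, j) else
        list(matrix(integer(0), ncol = 2L))
      for (a in inner) for (b in rest) {
        out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
      }
    }
    assign(key, out, envir = memo)
    out
  }
  if (n < 5L) return(list(matrix(integer(0), ncol = 2L)))
  rec(1L, n)
}

# independent count of valid structures (Nussinov-style counting recursion)
oracle_count <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  cnt <- matrix(1, n + 1L, n + 1L)  # cnt[i, j+1] over [i, j]; empty = 1
  get_cnt <- function(i, j) if (i > j) 1 else cnt[i, j + 1L]
  for (len in 5:max(5L, n)) {
    if (len > n) break
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      v <- get_cnt(i + 1L, j)
      for (k in (i + 4L):j) {
        if (oracle_can_pair(chars, i, k)) {
          v <- v + get_cnt(i + 1L, k - 1L) * get_cnt(k + 1L, j)
        }
      }
      cnt[i, j + 1L] <- v
    }
  }
  get_cnt(1L, n)
}

oracle_db <- function(pairs, n) {
  chars <- rep(".", n)
  if (nrow(pairs) > 0L) {
    chars[pairs[, 1L]] <- "("
    chars[pairs[, 2L]] <- ")"
  }
  paste(chars, collapse = "")
}

# pair+stack energy in kcal/mol, straight summation over defined terms
oracle_energy <- function(seq, pairs, gc = -3, au = -2, gu = -1,
                          stack = -1, pot = NULL) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  if (nrow(pairs) == 0L) return(0)
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  e <- 0
  key <- paste(pairs[, 1L], pairs[, 2L])
  for (r in seq_len(nrow(pairs))) {
    pr <- paste0(chars[pairs[r, 1L]], chars[pairs[r, 2L]])
    e <- e + switch(pr, GC = gc, CG = gc, AU = au, UA = au, GU = gu,
                    UG = gu, stop("non-canonical pair in oracle"))
    if (paste(pairs[r, 1L] + 1L, pairs[r, 2L] - 1L) %in% key) {
      e <- e + stack
    }
    if (!is.null(pot)) e <- e + pot[pairs[r, 1L], pairs[r, 2L]]
  }
  e
}

# exhaustive data.frame of (db, energy) for a sequence
oracle_landscape <- function(seq, pot = NULL) {
  structs <- oracle_enumerate(seq)
  n <- nchar(seq)
  db <- vapply(structs, oracle_db, character(1), n = n)
  energy <- vapply(structs, function(p) oracle_energy(seq, p, pot = pot),
                   numeric(1))
  o <- order(energy, db, method = "radix")
  data.frame(db = db[o], energy = energy[o], stringsAsFactors = FALSE)
}

oracle_pairs_from_db <- function(db) {
  chars <- strsplit(db, "", fixed = TRUE)[[1L]]
  open <- integer(0)
  out <- matrix(integer(0), ncol = 2L)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") open <- c(open, k)
    if (chars[k] == ")") {
      out <- rbind(out, c(open[length(open)], k))
      open <- open[-length(open)]
    }
  }
  out
}

# single base-pair move neighbours, brute-force scan
oracle_neighbors <- function(seq, db) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  pairs <- oracle_pairs_from_db(db)
  out <- character(0)
  for (r in seq_len(nrow(pairs))) {
    out <- c(out, oracle_db(pairs[-r, , drop = FALSE], n))
  }
  paired <- if (nrow(pairs) > 0L) c(pairs[, 1L], pairs[, 2L]) else integer(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i < 4L) next
      if (i %in% paired || j %in% paired) next
      if (!oracle_can_pair(chars, i, j)) next
      crossing <- FALSE
      for (r in seq_len(nrow(pairs))) {
        a <- pairs[r, 1L]; b <- pairs[r, 2L]
        if ((a < i && i < b && b < j) || (i < a && a < j && j < b)) {
          crossing <- TRUE
          break
        }
      }
      if (!crossing) out <- c(out, oracle_db(rbind(pairs, c(i, j)), n))
    }
  }
  out
}

# brute-force steepest descent with the byte-order lexicographic tie-break
oracle_walk <- function(seq, db, pot = NULL) {
  e_of <- function(d) oracle_energy(seq, oracle_pairs_from_db(d), pot = pot)
  cur <- db
  e_cur <- e_of(cur)
  repeat {
    nb <- oracle_neighbors(seq, cur)
    if (length(nb) == 0L) return(cur)
    e_nb <- vapply(nb, e_of, numeric(1))
    e_min <- min(e_nb)
    if (e_min >= e_cur) return(cur)
    cand <- sort(nb[e_nb == e_min], method = "radix")
    cur <- cand[1L]
    e_cur <- e_min
  }
}

# minimax (bottleneck) saddle heights over the full neighbour graph, via the
# minimum spanning tree: the largest edge weight on the MST path between two
# nodes equals the minimax path value; edge weight = max energy of its two
# endpoint structures, so path value = max structure energy along the path
oracle_minimax <- function(landscape, seq) {
  skip_if_not_installed("igraph")
  db <- landscape$db
  en <- landscape$energy
  idx <- stats::setNames(seq_along(db), db)
  edges <- list()
  for (k in seq_along(db)) {
    for (nbdb in oracle_neighbors(seq, db[k])) {
      j <- idx[nbdb]
      if (!is.na(j) && j > k) {
        edges[[length(edges) + 1L]] <- c(k, j, max(en[k], en[j]))
      }
    }
  }
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(em[, 1:2, drop = FALSE], directed = FALSE)
  igraph::E(g)$weight <- em[, 3L]
  mst <- igraph::mst(g)
  list(graph = mst, idx = idx, energy = en,
       saddle = function(db1, db2) {
         # the MST path is unique; find it topologically, then take the
         # largest (possibly negative) energy weight along it
         p <- igraph::shortest_paths(mst, idx[[db1]], idx[[db2]],
                                     weights = NA,
                                     output = "epath")$epath[[1L]]
         max(igraph::E(mst)$weight[as.integer(p)])
       })
}

# exact Boltzmann probabilities from an exhaustive landscape
oracle_probs <- function(landscape, beta) {
  w <- exp(-beta * (landscape$energy - min(landscape$energy)))
  stats::setNames(w / sum(w), landscape$db)
}

# empirical frequencies of a sample_set over a reference structure list
empirical_freq <- function(samples, dbs) {
  f <- stats::setNames(rep(0, length(dbs)), dbs)
  df <- samples$draws
  f[df$db] <- df$count / samples$n_total
  f
}

tv_distance <- function(p, q) 0.5 * sum(abs(p - q))

# chi-square goodness of fit with tail pooling (expected count >= 5)
chisq_pvalue <- function(counts, probs, n) {
  o <- order(probs, decreasing = TRUE)
  probs <- probs[o]; counts <- counts[o]
  exp_n <- probs * n
  pool <- exp_n < 5
  if (any(pool)) {
    counts <- c(counts[!pool], sum(counts[pool]))
    probs <- c(probs[!pool], sum(probs[pool]))
  }
  if (length(counts) < 2L) return(1)
  stat <- sum((counts - probs * n)^2 / (probs * n))
  stats::pchisq(stat, df = length(counts) - 1L, lower.tail = FALSE)
}

# saddle height implied by a barrier tree between two leaves: run the merge
# list (ascending) through a union-find and record when the two meet
tree_saddle_between <- function(tree, a, b) {
  ids <- stats::setNames(seq_len(nrow(tree$leaves)), tree$leaves$db)
  parent <- seq_len(nrow(tree$leaves))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  m <- tree$merges[order(tree$merges$saddle_energy), , drop = FALSE]
  for (r in seq_len(nrow(m))) {
    ra <- find(ids[[m$left_db[r]]]); rb <- find(ids[[m$right_db[r]]])
    if (ra != rb) parent[rb] <- ra
    if (find(ids[[a]]) == find(ids[[b]])) return(m$saddle_energy[r])
  }
  NA_real_
}
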