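# Independent reference implementations used as oracles.  These are
# deliberately written as plain quadratic/cubic scans, separate from the
# package's optimised code paths.

# O(n^2) greedy return-loop reference: enumerate all (i, j) pairs per bout
# and apply the same earliest-start / max-path-length / resume-after-end
# policy
oracle_segments <- function(trace, params = segment_params(),
                            gap_threshold = 60) {
  bouts <- split_bouts(trace, gap_threshold)
  out <- NULL
  for (b in seq_len(nrow(bouts))) {
    idx <- bouts$start[b]:(bouts$end[b] - 1L)
    if (length(idx) < 2) next
    xy <- trace$xy[idx, , drop = FALSE]
    tm <- trace$samples$time[idx]
    n <- length(idx)
    cum <- c(0, cumsum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)))
    i <- 1L
    while (i < n) {
      best_j <- -1L; best_len <- -Inf
      for (j in (i + 1):n) {
        dur <- tm[j] - tm[i]
        len <- cum[j] - cum[i]
        d <- sqrt(sum((xy[j, ] - xy[i, ])^2))
        ok <- d <= params$slack_radius &&
          dur >= params$min_duration && dur <= params$max_duration &&
          len >= params$min_length
        if (ok && (len > best_len ||
                   (len == best_len && j > best_j))) {
          best_len <- len; best_j <- j
        }
      }
      if (best_j > 0) {
        out <- rbind(out, c(idx[i], idx[best_j]))
        i <- best_j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  out
}

# all-windows stop reference with explicit loops
oracle_stops <- function(xy, time, static_radius = 10,
                         min_stop_duration = 60) {
  n <- length(time)
  durations <- c()
  i <- 1L
  while (i < n) {
    last <- i
    for (j in (i + 1):n) {
      if (sqrt(sum((xy[j, ] - xy[i, ])^2)) > static_radius) break
      last <- j
    }
    span <- time[last] - time[i]
    if (span >= min_stop_duration) {
      durations <- c(durations, span)
      i <- last + 1L
    } else {
      i <- i + 1L
    }
  }
  list(durations = durations, count = length(durations))
}

# sup-difference of the two empirical CDFs over the pooled values
oracle_ks_stat <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  Fa <- vapply(xs, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(xs, function(x) mean(b <= x), numeric(1))
  max(abs(Fa - Fb))
}

# BFS hop distances from one source over an adjacency list of integer ids
oracle_bfs <- function(adj, s) {
  n <- length(adj)
  d <- rep(Inf, n); d[s] <- 0
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- c()
    for (v in frontier) for (u in adj[[v]]) {
      if (is.infinite(d[u])) { d[u] <- d[v] + 1; nxt <- c(nxt, u) }
    }
    frontier <- unique(nxt)
  }
  d
}

# closeness / betweenness / degree centrality from first principles:
# all-pairs BFS distances, shortest-path counts by dynamic programming
# over nodes ordered by distance, Wasserman-Faust component scaling
oracle_centralities <- function(graph) {
  n <- igraph::vcount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  adj <- rep(list(integer(0)), n)
  for (e in seq_len(nrow(el))) {
    adj[[el[e, 1]]] <- c(adj[[el[e, 1]]], el[e, 2])
    adj[[el[e, 2]]] <- c(adj[[el[e, 2]]], el[e, 1])
  }
  d <- t(vapply(seq_len(n), function(s) oracle_bfs(adj, s), numeric(n)))
  # shortest-path counts sigma[s, t]
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(d[s, ])
    for (v in ord) {
      if (v == s || is.infinite(d[s, v])) next
      preds <- adj[[v]][d[s, adj[[v]]] == d[s, v] - 1]
      sigma[s, v] <- sum(sigma[s, preds])
    }
  }
  btw <- rep(0, n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || is.infinite(d[s, t])) next
      if (d[s, v] + d[v, t] == d[s, t] && sigma[s, t] > 0)
        btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  btw <- btw / ((n - 1) * (n - 2) / 2)
  clo <- vapply(seq_len(n), function(u) {
    reach <- which(is.finite(d[u, ]) & seq_len(n) != u)
    k <- length(reach) + 1
    if (k < 2) return(0)
    ((k - 1) / sum(d[u, reach])) * ((k - 1) / (n - 1))
  }, numeric(1))
  deg <- vapply(adj, function(a) length(unique(a)), numeric(1)) / (n - 1)
  data.frame(closeness = clo, betweenness = btw, degree_centrality = deg)
}

# reachability components over an adjacency list keyed by node name
oracle_components <- function(adj) {
  nodes <- names(adj)
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  k <- 0
  for (v in nodes) {
    if (!is.na(comp[v])) next
    k <- k + 1
    frontier <- v
    while (length(frontier) > 0) {
      comp[frontier] <- k
      frontier <- unique(unlist(adj[frontier]))
      frontier <- frontier[is.na(comp[frontier])]
    }
  }
  comp
}
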