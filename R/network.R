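#' Free-energy network of ligands and relative estimates
#'
#' Nodes are ligands (with optional experimental absolute binding free
#' energies, kcal/mol); directed edges carry relative estimates
#' `ddg = dG(to) - dG(from)` with uncertainties. Planned (not yet computed)
#' edges may have `NA` values.
#'
#' @param nodes data.frame with columns `id` and optionally `exp_dg`.
#' @param edges data.frame with columns `from`, `to`, and optionally `ddg`,
#'   `sigma`.
#' @return Object of class `fe_network`.
#' @export
fe_network <- function(nodes, edges) {
  if (is.character(nodes)) nodes <- data.frame(id = nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$exp_dg)) nodes$exp_dg <- NA_real_
  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  if (is.null(edges$ddg)) edges$ddg <- NA_real_
  if (is.null(edges$sigma)) edges$sigma <- NA_real_
  if (any(edges$from == edges$to)) stop("self-edges are not allowed")
  bad <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
  if (length(bad)) stop("edges reference unknown nodes: ", paste(bad, collapse = ", "))
  s <- edges$sigma[!is.na(edges$sigma)]
  if (length(s) && any(s <= 0)) stop("edge uncertainties must be positive")
  structure(list(nodes = nodes, edges = edges), class = "fe_network")
}

#' @export
print.fe_network <- function(x, ...) {
  cat(
    "fe_network:", nrow(x$nodes), "ligands,", nrow(x$edges), "edges (",
    sum(!is.na(x$edges$ddg)), "measured)\n"
  )
  invisible(x)
}

.edge_id <- function(edges) paste(edges$from, edges$to, sep = "->")

.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "~")
}

#' Build a star transformation map
#'
#' Connects every ligand to a reference ligand (edges directed
#' reference -> ligand), then appends extra edges to create cycles.
#' Duplicate extra edges (same unordered pair as an existing edge) are
#' rejected with a warning.
#'
#' @param ligands Character vector of ligand ids.
#' @param reference Reference ligand id (must be in `ligands`).
#' @param extra_edges Optional data.frame with columns `from`, `to`.
#' @return An [fe_network()] of planned edges.
#' @export
build_star_map <- function(ligands, reference, extra_edges = NULL) {
  if (!(reference %in% ligands)) stop("reference ligand not in ligand list")
  others <- setdiff(ligands, reference)
  edges <- data.frame(
    from = rep(reference, length(others)), to = others,
    stringsAsFactors = FALSE
  )
  if (!is.null(extra_edges) && nrow(extra_edges)) {
    have <- .pair_key(edges$from, edges$to)
    for (i in seq_len(nrow(extra_edges))) {
      k <- .pair_key(extra_edges$from[i], extra_edges$to[i])
      if (k %in% have) {
        warning(
          "duplicate edge ", extra_edges$from[i], " -> ", extra_edges$to[i],
          " rejected"
        )
        next
      }
      edges <- rbind(edges, extra_edges[i, c("from", "to")])
      have <- c(have, k)
    }
  }
  fe_network(data.frame(id = ligands, stringsAsFactors = FALSE), edges)
}

#' Build a multi-series transformation map
#'
#' Generates `intra_edges` transformations within each ligand series
#' (unordered pairs enumerated ring-wise by increasing separation) and
#' `inter_edges` transformations between every unordered pair of series
#' (round-robin endpoint pairing), e.g. 3 series x 10 intra + 3 pairs x 5
#' inter = 45 edges.
#'
#' @param series List of character vectors of ligand ids (one per series).
#' @param intra_edges Edges generated within each series.
#' @param inter_edges Edges generated between each pair of series.
#' @return An [fe_network()] of planned edges.
#' @export
build_series_map <- function(series, intra_edges, inter_edges) {
  all_ids <- unlist(series, use.names = FALSE)
  if (anyDuplicated(all_ids)) stop("ligand ids must be unique across series")
  edges <- data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  if (intra_edges > 0) for (s in series) {
    n <- length(s)
    if (intra_edges > choose(n, 2)) {
      stop("intra_edges (", intra_edges, ") exceeds possible pairs (", choose(n, 2), ")")
    }
    pairs <- list()
    seen <- character()
    for (gap in seq_len(n - 1)) {
      for (i in seq_len(n)) {
        j <- ((i + gap - 1) %% n) + 1
        k <- .pair_key(s[i], s[j])
        if (k %in% seen) next
        seen <- c(seen, k)
        pairs[[length(pairs) + 1]] <- c(s[i], s[j])
        if (length(pairs) == intra_edges) break
      }
      if (length(pairs) == intra_edges) break
    }
    edges <- rbind(edges, data.frame(
      from = vapply(pairs, `[`, "", 1),
      to = vapply(pairs, `[`, "", 2),
      stringsAsFactors = FALSE
    ))
  }
  ns <- length(series)
  if (ns > 1 && inter_edges > 0) {
    for (a in seq_len(ns - 1)) {
      for (b in (a + 1):ns) {
        sa <- series[[a]]
        sb <- series[[b]]
        for (k in seq_len(inter_edges)) {
          edges <- rbind(edges, data.frame(
            from = sa[((k - 1) %% length(sa)) + 1],
            to = sb[((k - 1) %% length(sb)) + 1],
            stringsAsFactors = FALSE
          ))
        }
      }
    }
  }
  fe_network(data.frame(id = all_ids, stringsAsFactors = FALSE), edges)
}

#' Enumerate simple cycles of a network
#'
#' All simple cycles of the underlying undirected graph (length >= 3), each
#' reported once, in deterministic lexicographic order of the node
#' sequence. Every cycle starts at its lexicographically smallest node and
#' proceeds toward its smaller neighbor.
#'
#' @param net An [fe_network()].
#' @param max_length Optional cap on cycle length.
#' @return List of character vectors of node ids (no repeated first node).
#' @export
enumerate_cycles <- function(net, max_length = NULL) {
  ids <- sort(net$nodes$id)
  adj <- lapply(ids, function(v) {
    nb <- c(
      net$edges$to[net$edges$from == v],
      net$edges$from[net$edges$to == v]
    )
    sort(unique(nb))
  })
  names(adj) <- ids
  cycles <- list()
  cap <- if (is.null(max_length)) length(ids) else max_length
  for (s in ids) {
    # DFS over paths s -> ... using only intermediate vertices > s
    stack <- list(list(path = s, last = s))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (nb in adj[[top$last]]) {
        if (nb == s && length(top$path) >= 3) {
          p <- top$path
          if (p[2] < p[length(p)]) {
            cycles[[length(cycles) + 1]] <- p
          }
        } else if (nb > s && !(nb %in% top$path) && length(top$path) < cap) {
          stack[[length(stack) + 1]] <- list(path = c(top$path, nb), last = nb)
        }
      }
    }
  }
  if (!length(cycles)) {
    return(list())
  }
  keys <- vapply(cycles, function(p) paste(p, collapse = "\r"), "")
  cycles[order(keys)]
}

#' Cycle closure of one ligand cycle
#'
#' Signed sum of the edge estimates around the cycle (an edge traversed
#' against its stored direction contributes with flipped sign), reported as
#' an absolute value, together with the per-edge normalized closure
#' `CC / sqrt(n)` (independent edge errors adding in quadrature) or `CC / n`
#' when `normalization = "n"`.
#'
#' @param cycle Character vector of node ids (as from [enumerate_cycles()]).
#' @param net An [fe_network()] with measured `ddg` on the cycle's edges.
#' @param normalization `"sqrt"` (default) or `"n"`.
#' @return List of class `cycle_report`: `cycle`, `n_edges`, `closure`,
#'   `normalized` (both kcal/mol).
#' @export
cycle_closure <- function(cycle, net, normalization = c("sqrt", "n")) {
  normalization <- match.arg(normalization)
  n <- length(cycle)
  if (n < 3) stop("a cycle needs at least 3 nodes")
  total <- 0
  for (i in seq_len(n)) {
    a <- cycle[i]
    b <- cycle[(i %% n) + 1]
    fwd <- which(net$edges$from == a & net$edges$to == b)
    rev <- which(net$edges$from == b & net$edges$to == a)
    if (length(fwd)) {
      total <- total + net$edges$ddg[fwd[1]]
    } else if (length(rev)) {
      total <- total - net$edges$ddg[rev[1]]
    } else {
      stop("cycle edge ", a, " - ", b, " missing from network")
    }
  }
  cc <- abs(total)
  structure(
    list(
      cycle = cycle, n_edges = n, closure = cc,
      normalized = if (normalization == "sqrt") cc / sqrt(n) else cc / n
    ),
    class = "cycle_report"
  )
}

#' Vote-based identification of unconverged edges
#'
#' Every edge collects +1 for each containing cycle whose normalized
#' closure exceeds `hi` (penalty) and -1 for each containing cycle whose
#' normalized closure is below `lo` (positive vote); edges are ranked by
#' descending vote sum (ties by edge id). Edges at the top of the ranking
#' are the prime suspects for sampling problems.
#'
#' @param cycles List of cycles (from [enumerate_cycles()]).
#' @param net An [fe_network()].
#' @param hi,lo Thresholds (kcal/mol) on the normalized closure.
#' @param normalization Passed to [cycle_closure()].
#' @return data.frame of class `vote_tally`: `edge`, `from`, `to`, `votes`,
#'   `n_cycles`, sorted by descending votes.
#' @export
vote_edges <- function(cycles, net, hi = 0.7, lo = 0.3,
                       normalization = c("sqrt", "n")) {
  if (hi <= lo) stop("hi threshold must exceed lo threshold")
  normalization <- match.arg(normalization)
  eid <- .edge_id(net$edges)
  votes <- stats::setNames(integer(length(eid)), eid)
  ncyc <- stats::setNames(integer(length(eid)), eid)
  for (cy in cycles) {
    rep <- cycle_closure(cy, net, normalization)
    n <- length(cy)
    members <- character()
    for (i in seq_len(n)) {
      a <- cy[i]
      b <- cy[(i %% n) + 1]
      hit <- which((net$edges$from == a & net$edges$to == b) |
        (net$edges$from == b & net$edges$to == a))
      members <- c(members, eid[hit[1]])
    }
    ncyc[members] <- ncyc[members] + 1L
    if (rep$normalized > hi) {
      votes[members] <- votes[members] + 1L
    } else if (rep$normalized < lo) {
      votes[members] <- votes[members] - 1L
    }
  }
  out <- data.frame(
    edge = eid, from = net$edges$from, to = net$edges$to,
    votes = as.integer(votes), n_cycles = as.integer(ncyc),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$votes, out$edge), ]
  rownames(out) <- NULL
  class(out) <- c("vote_tally", class(out))
  out
}

#' Hysteresis of a forward/reverse edge pair
#'
#' Discrepancy between an edge computed in the two opposite directions,
#' `|ddG(A->B) + ddG(B->A)|` (each value as reported in its own direction);
#' zero for perfectly converged transformations.
#'
#' @param ddg_forward,ddg_reverse Edge estimates (kcal/mol).
#' @return Hysteresis in kcal/mol.
#' @export
hysteresis <- function(ddg_forward, ddg_reverse) {
  abs(ddg_forward + ddg_reverse)
}

#' Maximum-likelihood absolute free energies from a relative network
#'
#' Weighted least squares: node values x minimize
#' `sum_edges (x_to - x_from - ddg)^2 / sigma^2`. The additive constant of
#' each connected component is fixed so that the mean prediction over its
#' experimentally measured nodes equals the mean of those experimental
#' values (components without experimental data are centered on zero, with
#' a warning, as is a disconnected network).
#'
#' @param net An [fe_network()] with measured edges.
#' @param experimental Optional named vector of experimental dG (kcal/mol);
#'   defaults to the network's `exp_dg` column.
#' @return data.frame with columns `id`, `dg`, `uncertainty`, `exp_dg`.
#' @export
solve_absolute_dg <- function(net, experimental = NULL) {
  nodes <- net$nodes
  if (!is.null(experimental)) {
    nodes$exp_dg <- experimental[nodes$id]
  }
  edges <- net$edges[!is.na(net$edges$ddg), , drop = FALSE]
  if (!nrow(edges)) stop("network has no measured edges")
  sigma <- ifelse(is.na(edges$sigma), 1, edges$sigma)
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")],
    directed = FALSE,
    vertices = nodes$id
  )
  comp <- igraph::components(g)
  if (comp$no > 1) warning("network is disconnected; solving per component")
  if (all(is.na(nodes$exp_dg))) {
    warning("no experimental anchors; absolute values centered on zero")
  }
  out <- data.frame(
    id = nodes$id, dg = NA_real_, uncertainty = NA_real_,
    exp_dg = nodes$exp_dg, stringsAsFactors = FALSE
  )
  membership <- comp$membership[nodes$id]
  for (cc in seq_len(comp$no)) {
    ids <- nodes$id[membership == cc]
    eidx <- which(edges$from %in% ids & edges$to %in% ids)
    x <- stats::setNames(rep(0, length(ids)), ids)
    if (length(eidx)) {
      A <- matrix(0, length(eidx), length(ids), dimnames = list(NULL, ids))
      for (r in seq_along(eidx)) {
        e <- eidx[r]
        A[r, edges$from[e]] <- -1
        A[r, edges$to[e]] <- 1
      }
      w <- 1 / sigma[eidx]^2
      AtWA <- t(A) %*% (A * w)
      AtWb <- t(A) %*% (edges$ddg[eidx] * w)
      cov <- MASS::ginv(AtWA)
      x[] <- as.numeric(cov %*% AtWb)
      out$uncertainty[match(ids, out$id)] <- sqrt(pmax(0, diag(cov)))
    } else {
      out$uncertainty[match(ids, out$id)] <- 0
    }
    anchors <- ids[!is.na(nodes$exp_dg[match(ids, nodes$id)])]
    shift <- if (length(anchors)) {
      mean(nodes$exp_dg[match(anchors, nodes$id)]) - mean(x[anchors])
    } else {
      -mean(x)
    }
    out$dg[match(ids, out$id)] <- x + shift
  }
  out
}

#' Benchmark statistics with bootstrap confidence intervals
#'
#' Error and correlation statistics between calculated and experimental
#' binding free energies, computed on mean-centered values (absolute
#' free-energy comparisons are defined up to a constant): RMSE, MUE,
#' R-squared (squared Pearson), Pearson rho,
#' `RAE = sum|calc - exp| / sum|exp - mean(exp)|`, and Kendall tau. 95%
#' confidence intervals come from a paired percentile bootstrap with a
#' fixed seed.
#'
#' @param calc,exp Paired numeric vectors (kcal/mol), length >= 3.
#' @param n_boot Bootstrap resamples.
#' @param seed RNG seed (bit-reproducible output).
#' @return data.frame of class `stats_report` with columns `metric`,
#'   `value`, `lower`, `upper`.
#' @export
benchmark_stats <- function(calc, exp, n_boot = 1000, seed = 1) {
  if (length(calc) != length(exp)) stop("calc and exp must be paired")
  if (length(calc) < 3) stop("need at least 3 paired values")
  if (!all(is.finite(calc)) || !all(is.finite(exp))) stop("values must be finite")
  one <- function(cv, ev) {
    c0 <- cv - mean(cv)
    e0 <- ev - mean(ev)
    denom <- sum(abs(e0))
    c(
      RMSE = sqrt(mean((c0 - e0)^2)),
      MUE = mean(abs(c0 - e0)),
      R2 = suppressWarnings(stats::cor(c0, e0))^2,
      rho = suppressWarnings(stats::cor(c0, e0)),
      RAE = if (denom > 0) sum(abs(c0 - e0)) / denom else NA_real_,
      KTAU = suppressWarnings(stats::cor(cv, ev, method = "kendall"))
    )
  }
  est <- one(calc, exp)
  set.seed(seed)
  n <- length(calc)
  boot <- matrix(NA_real_, n_boot, length(est))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot[b, ] <- one(calc[idx], exp[idx])
  }
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  out <- data.frame(
    metric = names(est), value = unname(est),
    lower = ci[1, ], upper = ci[2, ],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("stats_report", class(out))
  out
}
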