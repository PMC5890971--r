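# Airway stages: self-adapting region growing of the tracheobronchial tree,
# topology-preserving skeletonization, conversion of the skeleton to a
# rooted acyclic graph, and rule-based lobar labeling of the bronchi.

#' Segment the airway tree by self-adapting region growing
#'
#' Seeds in the tracheal air column (an air-density voxel in the most
#' cranial 10% of slices) and grows a 26-connected region under an HU
#' threshold that escalates from -950 HU in +10 HU steps. Each step re-grows
#' the region; the escalation stops before the step whose volume exceeds
#' `explosion_factor` times the previously accepted volume (the leak guard
#' that catches the flood into parenchyma), and the last accepted mask is
#' returned.
#'
#' @param ct A [ct_volume()].
#' @param start_hu,step_hu,max_hu Threshold escalation schedule (HU).
#' @param explosion_factor Volume ratio that triggers the leak guard.
#' @return Logical 3-D array (airway lumen mask) with a `spacing` attribute.
#' @export
segment_airway_tree <- function(ct, start_hu = -950, step_hu = 10,
                                max_hu = -400, explosion_factor = 1.5) {
  stopifnot(inherits(ct, "ct_volume"))
  d <- dim(ct$voxels)
  hu <- array(as.numeric(ct$voxels), d)

  ztop <- max(1L, ceiling(0.1 * d[1]))
  cand <- which(ct$voxels < -950 & slice.index(ct$voxels, 1) <= ztop)
  if (length(cand) == 0)
    stop_pulmo("no air-density seed found in the top 10% of slices",
               "seed_error")
  co <- which_voxels(array(seq_len(prod(d)) %in% cand, d))
  # seed: the candidate nearest the candidates' centroid in its best slice
  zbest <- as.integer(names(which.max(table(co[, 1]))))
  sl <- co[co[, 1] == zbest, , drop = FALSE]
  ctr <- colMeans(sl)
  seed0 <- sl[which.min(rowSums(sweep(sl, 2, ctr)^2)), ]
  seed <- seed0[1] + d[1] * (seed0[2] + d[2] * seed0[3])  # 0-based linear

  accepted <- .flood_leq(hu, as.integer(seed), start_hu)
  vol_prev <- sum(accepted)
  if (vol_prev == 0)
    stop_pulmo("seed voxel does not grow at the starting threshold",
               "seed_error")
  thr <- start_hu + step_hu
  while (thr <= max_hu) {
    mask <- .flood_leq(hu, as.integer(seed), thr)
    vol <- sum(mask)
    if (vol > explosion_factor * vol_prev) break
    accepted <- mask
    vol_prev <- vol
    thr <- thr + step_hu
  }
  accepted <- array(accepted, d)
  attr(accepted, "spacing") <- ct$spacing
  attr(accepted, "final_threshold") <- thr - step_hu
  accepted
}

#' Skeletonize a binary mask
#'
#' Sequential topology-preserving 3-D thinning (six border-direction
#' subiterations, simple-point deletion tests, 26-connected foreground /
#' 6-connected background). The result is a subset of the input, one voxel
#' thick, with the same number of 26-connected components. Curve endpoints
#' are preserved; the centerline ends of blunt tubes retract by up to the
#' local tube radius, as for any curve-thinning scheme.
#'
#' @param mask Logical 3-D array.
#' @return Logical 3-D array (the skeleton), `spacing` attribute preserved.
#' @export
skeletonize <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop_pulmo("mask must be a 3-D array", "dim_error")
  if (!any(mask)) stop_pulmo("cannot skeletonize an empty mask", "empty_input")
  out <- array(.thin3d(mask), dim(mask))
  attr(out, "spacing") <- attr(mask, "spacing")
  out
}

# ---- skeleton -> graph -----------------------------------------------------

#' Build a rooted acyclic airway graph from a skeleton
#'
#' Skeleton voxels with other than two 26-neighbors become nodes (clusters
#' of adjacent junction voxels are merged into a single node); maximal
#' degree-2 chains become edges carrying their voxel chain, physical length,
#' and mean radius (from the distance transform of the airway mask). Spur
#' edges shorter than `spur_mm` that end in an endpoint are pruned, residual
#' cycles are broken by removing their longest edge, and the root is the
#' endpoint with the largest mean radius among the most cranial 10% of
#' nodes. Edge generations count bifurcations from the root (root edge = 0).
#'
#' @param skeleton Logical 3-D array from [skeletonize()].
#' @param mask The airway mask the skeleton came from (radius estimation).
#' @param spacing Voxel spacing in mm (z, y, x).
#' @param spur_mm Pruning length for terminal spurs.
#' @return An `airway_graph` object.
#' @export
build_airway_graph <- function(skeleton, mask, spacing, spur_mm = 3) {
  if (!any(skeleton)) stop_pulmo("empty skeleton", "empty_input")
  d <- dim(skeleton)
  vox <- which_voxels(skeleton)                 # 0-based (z,y,x)
  lin <- voxel_index(vox, d)                    # 1-based linear
  nvox <- nrow(vox)

  # adjacency among skeleton voxels (26-connectivity), vectorized per offset
  pos <- seq_len(nvox)
  lookup <- rep(NA_integer_, prod(d))
  lookup[lin] <- pos
  adj_from <- integer(0); adj_to <- integer(0)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    nz <- vox[, 1] + dz; ny <- vox[, 2] + dy; nx <- vox[, 3] + dx
    ok <- nz >= 0 & nz < d[1] & ny >= 0 & ny < d[2] & nx >= 0 & nx < d[3]
    nl <- 1L + nz[ok] + d[1] * (ny[ok] + d[2] * nx[ok])
    hit <- lookup[nl]
    sel <- !is.na(hit)
    adj_from <- c(adj_from, pos[ok][sel])
    adj_to <- c(adj_to, hit[sel])
  }
  deg <- tabulate(adj_from, nbins = nvox)
  adj <- split(adj_to, factor(adj_from, levels = pos))

  # radius from the mask's interior distance transform
  dist_bg <- sqrt(.edt_sq(!mask, as.numeric(spacing)))
  radius_vox <- dist_bg[lin]

  # node ids: junction clusters (deg >= 3) merged; endpoints (deg <= 1) single
  node_id <- integer(nvox)
  nid <- 0L
  is_junction <- deg >= 3L
  visited <- logical(nvox)
  for (v in pos[is_junction]) {
    if (visited[v]) next
    nid <- nid + 1L
    stack <- v; visited[v] <- TRUE
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      node_id[u] <- nid
      nb <- adj[[u]]
      nb <- nb[is_junction[nb] & !visited[nb]]
      visited[nb] <- TRUE
      stack <- c(stack, nb)
    }
  }
  for (v in pos[deg <= 1L]) { nid <- nid + 1L; node_id[v] <- nid }

  # trace chains between nodes
  edges <- list()
  echains <- list()
  seen_pair <- new.env(hash = TRUE)
  used_chain <- logical(nvox)
  add_edge <- function(a, b, chain) {
    edges[[length(edges) + 1L]] <<- c(a, b)
    echains[[length(echains) + 1L]] <<- chain
  }
  for (v in pos[node_id > 0L]) {
    for (w in adj[[v]]) {
      if (node_id[w] > 0L) {
        if (node_id[w] == node_id[v]) next            # intra-cluster
        pk <- paste(min(v, w), max(v, w))
        if (!is.null(seen_pair[[pk]])) next
        seen_pair[[pk]] <- TRUE
        add_edge(node_id[v], node_id[w], c(v, w))
      } else if (!used_chain[w]) {
        chain <- c(v, w)
        used_chain[w] <- TRUE
        prev <- v; cur <- w
        repeat {
          nxt <- adj[[cur]]
          nxt <- nxt[nxt != prev]
          if (length(nxt) == 0) break                  # dangling chain end
          # prefer a node voxel; otherwise continue along the chain
          nd <- nxt[node_id[nxt] > 0L]
          if (length(nd)) { chain <- c(chain, nd[1]); cur <- nd[1]; break }
          nxt <- nxt[!used_chain[nxt]]
          if (length(nxt) == 0) break
          used_chain[nxt[1]] <- TRUE
          chain <- c(chain, nxt[1])
          prev <- cur; cur <- nxt[1]
        }
        if (node_id[cur] > 0L && node_id[cur] != 0L)
          add_edge(node_id[v], node_id[cur], chain)
      }
    }
  }

  # node table: centroid of member voxels
  nodes <- data.frame(id = seq_len(nid))
  nodes$z <- vapply(nodes$id, function(i) mean(vox[node_id == i, 1]), numeric(1))
  nodes$y <- vapply(nodes$id, function(i) mean(vox[node_id == i, 2]), numeric(1))
  nodes$x <- vapply(nodes$id, function(i) mean(vox[node_id == i, 3]), numeric(1))

  chain_len <- function(chain) {
    if (length(chain) < 2) return(0)
    p <- sweep(vox[chain, , drop = FALSE], 2, as.numeric(spacing), `*`)
    sum(sqrt(rowSums(diff(p)^2)))
  }
  ed <- data.frame(
    from = vapply(edges, `[`, numeric(1), 1),
    to = vapply(edges, `[`, numeric(1), 2))
  ed$length_mm <- vapply(echains, chain_len, numeric(1))
  ed$radius_mm <- vapply(echains, function(ch) mean(radius_vox[ch]), numeric(1))

  g <- igraph::graph_from_data_frame(
    cbind(ed[, c("from", "to")], eid = seq_len(nrow(ed))),
    directed = FALSE, vertices = nodes)

  # prune short terminal spurs
  repeat {
    degs <- igraph::degree(g)
    eids <- igraph::E(g)$eid
    drop <- integer(0)
    for (i in seq_along(eids)) {
      ends <- igraph::ends(g, i)
      term <- degs[ends[1]] == 1 || degs[ends[2]] == 1
      if (term && ed$length_mm[eids[i]] < spur_mm && igraph::ecount(g) > 1)
        drop <- c(drop, i)
    }
    if (length(drop) == 0) break
    g <- igraph::delete_edges(g, drop[1])   # one at a time: degrees change
    iso <- which(igraph::degree(g) == 0)
    if (length(iso)) g <- igraph::delete_vertices(g, iso)
  }

  # pruning can leave pass-through nodes (former junctions whose side
  # branches are gone): merge their two incident edges into one chain
  node_of_voxel <- node_id
  repeat {
    degs <- igraph::degree(g)
    v2 <- which(degs == 2)
    if (length(v2) == 0) break
    v <- v2[1]
    ie <- as.integer(igraph::incident(g, v))
    if (length(ie) != 2) break
    eids <- igraph::edge_attr(g, "eid", igraph::E(g)[ie])
    vname <- as.integer(igraph::V(g)$name[v])
    orient <- function(ch, at_end) {
      # orient a chain so that the voxel belonging to node `vname` sits at
      # the requested end
      if (node_of_voxel[ch[1]] == vname && at_end) rev(ch)
      else if (node_of_voxel[ch[length(ch)]] == vname && !at_end) rev(ch)
      else ch
    }
    ch1 <- orient(echains[[eids[1]]], at_end = TRUE)
    ch2 <- orient(echains[[eids[2]]], at_end = FALSE)
    merged <- c(ch1, ch2[-1])
    echains[[length(echains) + 1L]] <- merged
    new_eid <- length(echains)
    ed <- rbind(ed, data.frame(
      from = node_of_voxel[merged[1]],
      to = node_of_voxel[merged[length(merged)]],
      length_mm = chain_len(merged),
      radius_mm = mean(radius_vox[merged])))
    nb <- as.integer(igraph::neighbors(g, v))
    if (length(unique(nb)) < 2) break   # would create a self-loop
    g <- igraph::add_edges(g, nb, attr = list(eid = new_eid))
    g <- igraph::delete_vertices(g, v)
  }

  # break residual cycles: drop the longest edge of the shortest cycle found
  while (igraph::ecount(g) >= igraph::vcount(g)) {
    gr <- igraph::girth(g)
    cyc_v <- gr$circle
    if (length(cyc_v) < 1) break
    sub_e <- igraph::E(g, path = c(cyc_v, cyc_v[1]))
    lens <- ed$length_mm[igraph::edge_attr(g, "eid", sub_e)]
    g <- igraph::delete_edges(g, sub_e[which.max(lens)])
  }

  # root: endpoint with largest incident mean radius among most cranial 10%
  vz <- igraph::V(g)$z
  keepz <- vz <= stats::quantile(vz, 0.10)
  cand <- which(keepz & igraph::degree(g) == 1)
  if (length(cand) == 0) cand <- which.min(vz)
  rad_of <- vapply(cand, function(v) {
    ie <- igraph::incident(g, v)
    max(ed$radius_mm[igraph::edge_attr(g, "eid", ie)])
  }, numeric(1))
  root <- cand[which.max(rad_of)]

  # orient from the root, assign generations
  ne <- igraph::ecount(g)
  eid_in_g <- igraph::E(g)$eid
  out_edges <- data.frame(
    eid = eid_in_g, from = NA_integer_, to = NA_integer_,
    generation = NA_integer_,
    length_mm = ed$length_mm[eid_in_g], radius_mm = ed$radius_mm[eid_in_g],
    label = "unlabeled", code = 0L, stringsAsFactors = FALSE)
  vnames <- as.integer(igraph::V(g)$name)
  visited_v <- logical(igraph::vcount(g))
  queue <- list(list(v = root, gen = 0L))
  visited_v[root] <- TRUE
  while (length(queue)) {
    it <- queue[[1]]; queue <- queue[-1]
    ie <- as.integer(igraph::incident(g, it$v))
    branches <- 0L
    for (i in ie) {
      ends <- as.integer(igraph::ends(g, i, names = FALSE))
      w <- if (ends[1] == it$v) ends[2] else ends[1]
      if (visited_v[w]) next
      visited_v[w] <- TRUE
      branches <- branches + 1L
      row <- which(out_edges$eid == eid_in_g[i])
      out_edges$from[row] <- vnames[it$v]
      out_edges$to[row] <- vnames[w]
      out_edges$generation[row] <- it$gen
      child_gen <- it$gen + 1L
      queue[[length(queue) + 1L]] <- list(v = w, gen = child_gen)
    }
  }

  # orient chains from->to and attach
  chains <- vector("list", nrow(out_edges))
  for (i in seq_len(nrow(out_edges))) {
    ch <- echains[[out_edges$eid[i]]]
    first_nid <- node_id[ch[1]]
    if (!is.na(out_edges$from[i]) && first_nid != out_edges$from[i])
      ch <- rev(ch)
    chains[[i]] <- vox[ch, , drop = FALSE]
  }

  nodes$type <- "bifurcation"
  degs <- igraph::degree(g)
  nodes_in_g <- as.integer(igraph::V(g)$name)
  nodes <- nodes[nodes$id %in% nodes_in_g, , drop = FALSE]
  nodes$type <- ifelse(degs[match(nodes$id, nodes_in_g)] == 1, "endpoint",
                       "bifurcation")
  nodes$type[nodes$id == vnames[root]] <- "root"

  structure(list(
    nodes = nodes, edges = out_edges, chains = chains,
    root = vnames[root], spacing = as.numeric(spacing), dims = d),
    class = "airway_graph")
}

#' @export
print.airway_graph <- function(x, ...) {
  labs <- table(x$edges$label)
  cat(sprintf("<airway_graph> %d nodes, %d edges, root node %d\n",
              nrow(x$nodes), nrow(x$edges), x$root))
  cat("  labels:", paste(sprintf("%s=%d", names(labs), labs), collapse = " "),
      "\n")
  invisible(x)
}

graph_children <- function(graph, node) which(graph$edges$from == node)

edge_direction <- function(graph, i) {
  nf <- graph$nodes[match(graph$edges$from[i], graph$nodes$id), c("z", "y", "x")]
  nt <- graph$nodes[match(graph$edges$to[i], graph$nodes$id), c("z", "y", "x")]
  u <- (unlist(nt) - unlist(nf)) * graph$spacing
  l <- sqrt(sum(u^2))
  if (l == 0) u else u / l
}

#' Label the lobar bronchi of an airway graph
#'
#' Anatomical rule set: the root edge is the trachea; its two children split
#' into left/right main bronchus by the lateral (x) component of their
#' direction. On the right, the child of the main bronchus with the largest
#' superior+lateral direction component is the right upper lobe bronchus and
#' the continuation is the bronchus intermedius, whose anterior-most child
#' is the middle lobe bronchus and whose inferior continuation the lower
#' lobe bronchus. On the left, the superior child is the upper lobe
#' bronchus (its anteroinferior sub-branch the lingular bronchus) and the
#' inferior child the lower lobe bronchus. Ties are broken by the larger
#' mean radius. Edges distal to a labeled lobar bronchus inherit its code;
#' subtrees the rules cannot place are assigned by endpoint position
#' quantiles (the fallback that stands in for rules covering anatomical
#' variants). Missing branches are tolerated: absent lobes simply yield no
#' edges of that code.
#'
#' @param graph An `airway_graph` from [build_airway_graph()].
#' @return The graph with `label` and `code` filled in on its edges.
#' @export
label_lobar_bronchi <- function(graph) {
  stopifnot(inherits(graph, "airway_graph"))
  ed <- graph$edges
  ed$label <- "unlabeled"
  ed$code <- 0L
  if (max(ed$generation, na.rm = TRUE) < 1)
    stop_pulmo("graph has fewer than 2 generations; cannot label",
               "labeling_error")

  root_edges <- which(ed$from == graph$root)
  if (length(root_edges) != 1)
    stop_pulmo(sprintf("expected a single trachea edge at the root, found %d",
                       length(root_edges)), "labeling_error")
  tr <- root_edges[1]
  ed$label[tr] <- "trachea"

  carina <- ed$to[tr]
  ch <- graph_children(graph, carina)
  if (length(ch) < 2)
    stop_pulmo(sprintf(
      "fewer than 2 children at the carina (%d nodes, %d edges)",
      nrow(graph$nodes), nrow(ed)), "labeling_error")
  dirs <- t(vapply(ch, function(i) edge_direction(graph, i), numeric(3)))
  main_L <- ch[which.max(dirs[, 3])]
  main_R <- ch[which.min(dirs[, 3])]
  ed$label[main_L] <- "main_L"
  ed$label[main_R] <- "main_R"

  pick <- function(cand, score) {
    # largest score; ties broken by larger radius
    o <- order(-score, -ed$radius_mm[cand])
    cand[o[1]]
  }

  # right side
  rch <- graph_children(graph, ed$to[main_R])
  bi <- NA_integer_
  if (length(rch) == 1) {
    bi <- rch
  } else if (length(rch) >= 2) {
    rd <- t(vapply(rch, function(i) edge_direction(graph, i), numeric(3)))
    rul <- pick(rch, -rd[, 1] - rd[, 3])          # superior + lateral (right)
    ed$label[rul] <- "RUL"; ed$code[rul] <- 1L
    rest <- setdiff(rch, rul)
    rd2 <- t(vapply(rest, function(i) edge_direction(graph, i), numeric(3)))
    bi <- pick(rest, rd2[, 1])                    # inferior continuation
  }
  if (!is.na(bi) && ed$code[bi] == 0L) {
    ed$label[bi] <- "bronchus_intermedius"
    bch <- graph_children(graph, ed$to[bi])
    if (length(bch) == 1) {
      ed$label[bch] <- "RLL"; ed$code[bch] <- 3L
    } else if (length(bch) >= 2) {
      bd <- t(vapply(bch, function(i) edge_direction(graph, i), numeric(3)))
      rml <- pick(bch, -bd[, 2])                  # anterior-most
      ed$label[rml] <- "RML"; ed$code[rml] <- 2L
      rest <- setdiff(bch, rml)
      bd2 <- t(vapply(rest, function(i) edge_direction(graph, i), numeric(3)))
      rll <- pick(rest, bd2[, 1])                 # inferior
      ed$label[rll] <- "RLL"; ed$code[rll] <- 3L
    }
  }

  # left side
  lch <- graph_children(graph, ed$to[main_L])
  if (length(lch) == 1) {
    ld <- edge_direction(graph, lch)
    if (ld[1] < 0) { ed$label[lch] <- "LUL"; ed$code[lch] <- 4L }
    else { ed$label[lch] <- "LLL"; ed$code[lch] <- 6L }
  } else if (length(lch) >= 2) {
    ld <- t(vapply(lch, function(i) edge_direction(graph, i), numeric(3)))
    lul <- pick(lch, -ld[, 1])                    # superior
    ed$label[lul] <- "LUL"; ed$code[lul] <- 4L
    rest <- setdiff(lch, lul)
    ld2 <- t(vapply(rest, function(i) edge_direction(graph, i), numeric(3)))
    lll <- pick(rest, ld2[, 1])                   # inferior
    ed$label[lll] <- "LLL"; ed$code[lll] <- 6L
    # lingula: anteroinferior sub-branch of the upper lobe bronchus
    uch <- graph_children(graph, ed$to[lul])
    if (length(uch) >= 2) {
      ud <- t(vapply(uch, function(i) edge_direction(graph, i), numeric(3)))
      sc <- ud[, 1] - ud[, 2]                     # inferior + anterior
      lli <- pick(uch, sc)
      if ((ud[, 1] - ud[, 2])[match(lli, uch)] > 0) {
        ed$label[lli] <- "LLi"; ed$code[lli] <- 5L
      }
    }
  }

  # inherit codes downstream (breadth-first from every labeled lobar edge)
  repeat {
    grew <- FALSE
    for (i in seq_len(nrow(ed))) {
      if (ed$code[i] == 0L) next
      for (j in graph_children(graph, ed$to[i])) {
        if (ed$code[j] == 0L && ed$label[j] == "unlabeled") {
          ed$code[j] <- ed$code[i]
          ed$label[j] <- names(lobe_codes())[ed$code[i]]
          grew <- TRUE
        }
      }
    }
    if (!grew) break
  }

  # fallback: place leftover distal subtrees by endpoint position quantiles
  unl <- which(ed$label == "unlabeled")
  if (length(unl)) {
    node_z <- graph$nodes$z
    zq <- stats::quantile(node_z, c(0.35, 0.5))
    xmid <- stats::median(graph$nodes$x)
    for (i in unl) {
      nt <- graph$nodes[match(ed$to[i], graph$nodes$id), ]
      right_side <- nt$x < xmid
      code <- if (right_side) {
        if (nt$z < zq[1]) 1L else if (nt$y < stats::median(graph$nodes$y)) 2L else 3L
      } else {
        if (nt$z < zq[2]) 4L else 6L
      }
      ed$code[i] <- code
      ed$label[i] <- names(lobe_codes())[code]
    }
  }

  graph$edges <- ed
  graph
}

# centerline voxels (0-based z,y,x) carrying a given lobar code
graph_code_voxels <- function(graph, code) {
  sel <- which(graph$edges$code == code)
  if (length(sel) == 0) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, graph$chains[sel])
}

#' Serialize an airway graph to JSON
#'
#' @param graph An `airway_graph`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_airway_graph <- function(graph, path) {
  out <- list(
    root = graph$root,
    spacing = graph$spacing,
    nodes = graph$nodes,
    edges = graph$edges[, c("from", "to", "length_mm", "radius_mm",
                            "generation", "label", "code")],
    chains = lapply(graph$chains, function(m) unname(as.matrix(m))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
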