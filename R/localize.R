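## Glycan site localization on the electron-activation scan.
##
## The localization graph has nodes (i, c): backbone position i (0..L) and
## child box c, the sub-multiset of the PSM's glycan box already placed on
## sites <= i. Edges keep c fixed between candidate sites and may add one
## glycan at an S/T. Every root-to-sink path is exactly one full assignment
## of the box to sites. Node (i, c) is scored by counting matched c- and
## z-dot ions (1+/2+) whose glycan load is mass(c) / mass(box - c); site
## probabilities follow from exponentially weighted path sums computed by a
## forward-backward pass (no path enumeration).

#' Build a localization graph
#'
#' @param sequence Peptide sequence.
#' @param mods Named mod-delta vector (position -> Da).
#' @param box A glycan box (from [enumerate_boxes()]): `idx` into `db`.
#' @param db The `glycan_db` the box indexes.
#' @param scan The electron-activation `glyco_spectrum` (may have no peaks).
#' @param product_tol_ppm Fragment tolerance (ppm).
#' @return List of class `loc_graph`: peptide geometry, child-box table,
#'   per-position/child score matrix and theoretical-ion arrays.
#' @export
build_graph <- function(sequence, mods, box, db, scan, product_tol_ppm = 10) {
  L <- nchar(sequence)
  sites <- which(strsplit(sequence, "", fixed = TRUE)[[1]] %in% c("S", "T"))
  if (box$n_glycans > length(sites)) {
    stop("infeasible box: ", box$n_glycans, " glycans but only ",
         length(sites), " candidate site(s)")
  }
  tb <- table(box$idx)
  entry <- as.integer(names(tb))       # distinct db entries in the box
  mult <- as.integer(tb)
  d <- length(entry)
  # child boxes: all count vectors 0..mult per distinct entry
  grid <- do.call(expand.grid, c(lapply(mult, function(m) 0:m),
                                 KEEP.OUT.ATTRS = FALSE))
  child <- as.matrix(grid)             # nChild x d
  colnames(child) <- NULL
  nChild <- nrow(child)
  child_mass <- as.numeric(child %*% db$mass[entry])
  child_size <- rowSums(child)
  box_mass <- box$mass
  # child index lookup: key by mixed-radix code
  radix <- cumprod(c(1L, (mult + 1L)[-d]))
  code <- as.integer(child %*% radix)  # 0-based codes, == row - 1 by expand.grid
  stopifnot(all(code == seq_len(nChild) - 1L))
  child_of <- function(cnt) as.integer(sum(cnt * radix)) + 1L
  # theoretical ions and score matrix: positions 1..L-1
  S <- matrix(0L, nrow = L, ncol = nChild)          # row L stays 0 (sink)
  theo <- array(NA_real_, dim = c(L, nChild, 4L))   # c1+, c2+, z1+, z2+
  matched <- array(FALSE, dim = c(L, nChild, 4L))
  if (L >= 2L) {
    pre <- .prefix_masses(sequence, mods)
    total <- pre[L]
    for (ci in seq_len(nChild)) {
      g <- child_mass[ci]
      for (i in seq_len(L - 1L)) {
        cm <- pre[i] + NH3_MASS + g
        zm <- (total - pre[i]) + WATER_MASS - NH3_MASS + .ELEMENT_MASS[["H"]] +
          (box_mass - g)
        theo[i, ci, ] <- c((cm + PROTON_MASS), (cm + 2 * PROTON_MASS) / 2,
                           (zm + PROTON_MASS), (zm + 2 * PROTON_MASS) / 2)
      }
    }
    if (length(scan$mz)) {
      for (ci in seq_len(nChild)) {
        for (k in 1:4) {
          m <- match_peaks(theo[seq_len(L - 1L), ci, k], scan$mz, product_tol_ppm)
          matched[seq_len(L - 1L), ci, k] <- !is.na(m)
        }
      }
      S[seq_len(L - 1L), ] <- apply(matched[seq_len(L - 1L), , , drop = FALSE],
                                    c(1, 2), sum)
    }
  }
  structure(list(sequence = sequence, mods = mods, L = L, sites = sites,
                 box = box, db = db, entry = entry, mult = mult,
                 child = child, child_mass = child_mass,
                 child_size = child_size, child_of = child_of,
                 nChild = nChild, S = S, theo = theo, matched = matched,
                 product_tol_ppm = product_tol_ppm),
            class = "loc_graph")
}

## Transition structure: for each child index, the list of (parent index,
## which distinct entry was added).
.parents_of <- function(g) {
  out <- vector("list", g$nChild)
  for (ci in seq_len(g$nChild)) {
    cnt <- g$child[ci, ]
    ps <- list()
    for (j in seq_along(cnt)) {
      if (cnt[j] > 0L) {
        p <- cnt
        p[j] <- p[j] - 1L
        ps[[length(ps) + 1L]] <- c(parent = g$child_of(p), entry = j)
      }
    }
    out[[ci]] <- ps
  }
  out
}

#' Localize a glycan box from its graph
#'
#' Computes, by a forward-backward pass over the localization graph: the best
#' path score (maximum matched-ion count over full assignments), exact site
#' probabilities under exponential path weighting `base^score`, the number of
#' distinct configurations, and a confidence level:
#' \describe{
#'   \item{1}{all glycans localized (site probability > `prob_threshold`)
#'     with at least one matched site-determining ion on the best path;}
#'   \item{1b}{all glycans localized, but by process of elimination — the
#'     assignment is forced (one configuration) or no site-determining ion
#'     was matched;}
#'   \item{2}{at least one but not all glycans confidently localized;}
#'   \item{3}{no glycan confidently localized.}
#' }
#'
#' @param graph A `loc_graph` from [build_graph()].
#' @param weighting_base Base of the path weighting (default 10: one extra
#'   site-determining ion takes a two-way split to ~0.91).
#' @param prob_threshold Confidence threshold on site probability.
#' @return List of class `loc_result`: `best_assignment` (named integer,
#'   `"S3"`-style site label -> db entry index), `best_path_score`,
#'   `site_probabilities` (matrix sites x distinct entries),
#'   `n_configurations`, `n_site_determining`, `level`, `opair_score`.
#' @export
localize <- function(graph, weighting_base = 10, prob_threshold = 0.75) {
  g <- graph
  L <- g$L
  nC <- g$nChild
  is_site <- logical(L)
  is_site[g$sites] <- TRUE
  parents <- .parents_of(g)
  full <- nC                       # expand.grid: last row is the full box
  W <- weighting_base^g$S          # node weights, rows 1..L
  # forward: Fm[i+1, c] = sum over root->(i,c) paths of prod W(nodes 1..i)
  Fm <- matrix(0, L + 1L, nC)
  Cnt <- matrix(0, L + 1L, nC)     # path counts (reachability + n_config)
  Vm <- matrix(-Inf, L + 1L, nC)   # best cumulative score
  Arg <- matrix(NA_integer_, L + 1L, nC)  # backtrack: previous child
  Fm[1L, 1L] <- 1
  Cnt[1L, 1L] <- 1
  Vm[1L, 1L] <- 0
  for (i in seq_len(L)) {
    for (ci in seq_len(nC)) {
      acc <- Fm[i, ci]
      cnt <- Cnt[i, ci]
      best <- Vm[i, ci]
      argc <- ci
      if (is_site[i]) {
        for (pe in parents[[ci]]) {
          p <- pe[["parent"]]
          acc <- acc + Fm[i, p]
          cnt <- cnt + Cnt[i, p]
          if (Vm[i, p] > best) {
            best <- Vm[i, p]
            argc <- p
          }
        }
      }
      Fm[i + 1L, ci] <- acc * W[i, ci]
      Cnt[i + 1L, ci] <- cnt
      Vm[i + 1L, ci] <- if (is.finite(best)) best + g$S[i, ci] else -Inf
      Arg[i + 1L, ci] <- argc
    }
  }
  # backward: Bm[i+1, c] = sum over (i,c)->sink paths of prod W(nodes i+1..L)
  Bm <- matrix(0, L + 1L, nC)
  Bcnt <- matrix(0, L + 1L, nC)
  Bm[L + 1L, full] <- 1
  Bcnt[L + 1L, full] <- 1
  children_of <- vector("list", nC)  # inverse of parents: child states reachable
  for (ci in seq_len(nC)) {
    for (pe in parents[[ci]]) {
      p <- pe[["parent"]]
      children_of[[p]] <- c(children_of[[p]], ci)
    }
  }
  for (i in rev(seq_len(L))) {
    for (ci in seq_len(nC)) {
      acc <- Bm[i + 1L, ci] * W[i, ci]
      cnt <- Bcnt[i + 1L, ci]
      if (is_site[i]) {
        for (ch in children_of[[ci]]) {
          acc <- acc + Bm[i + 1L, ch] * W[i, ch]
          cnt <- cnt + Bcnt[i + 1L, ch]
        }
      }
      Bm[i, ci] <- acc
      Bcnt[i, ci] <- cnt
    }
  }
  Z <- Fm[L + 1L, full]
  n_config <- Cnt[L + 1L, full]
  best_score <- Vm[L + 1L, full]
  # site probabilities: P(site p carries distinct entry j)
  d <- length(g$entry)
  P <- matrix(0, length(g$sites), d,
              dimnames = list(paste0(substring(g$sequence, g$sites, g$sites),
                                     g$sites),
                              g$db$text[g$entry]))
  for (si in seq_along(g$sites)) {
    p <- g$sites[si]
    for (ci in seq_len(nC)) {
      for (pe in parents[[ci]]) {
        contrib <- Fm[p, pe[["parent"]]] * W[p, ci] * Bm[p + 1L, ci]
        if (contrib > 0) P[si, pe[["entry"]]] <- P[si, pe[["entry"]]] + contrib
      }
    }
  }
  P <- P / Z
  # best path backtrack (ties: lowest child index, deterministic)
  path <- integer(L + 1L)
  path[L + 1L] <- full
  for (i in rev(seq_len(L))) path[i] <- Arg[i + 1L, path[i + 1L]]
  # best assignment: entry added at each site along the path
  assign <- stats::setNames(integer(0), character(0))
  for (si in seq_along(g$sites)) {
    p <- g$sites[si]
    before <- path[p]
    after <- path[p + 1L]
    if (after != before) {
      dj <- which(g$child[after, ] - g$child[before, ] == 1L)
      assign[rownames(P)[si]] <- g$entry[dj]
    }
  }
  # site-determining matched ions along the best path: a matched ion at
  # (i, c) counts when its theoretical m/z differs from the same ion slot of
  # another feasible child at i.
  n_sd <- 0L
  if (L >= 2L) {
    for (i in seq_len(L - 1L)) {
      ci <- path[i + 1L]
      feas <- which(Cnt[i + 1L, ] > 0 & Bcnt[i + 1L, ] > 0)
      if (length(feas) < 2L) next
      for (k in 1:4) {
        if (!g$matched[i, ci, k]) next
        if (any(abs(g$theo[i, feas, k] - g$theo[i, ci, k]) > 1e-6)) {
          n_sd <- n_sd + 1L
        }
      }
    }
  }
  # localization status per distinct entry
  n_loc <- vapply(seq_len(d), function(j)
    min(g$mult[j], sum(P[, j] > prob_threshold)), numeric(1))
  all_loc <- sum(n_loc) >= g$box$n_glycans
  any_loc <- sum(n_loc) > 0
  level <- if (all_loc) {
    if (n_config == 1 || n_sd == 0L) "1b" else "1"
  } else if (any_loc) "2" else "3"
  structure(list(best_assignment = assign, best_path_score = best_score,
                 site_probabilities = P, n_configurations = n_config,
                 n_site_determining = n_sd, level = level,
                 opair_score = best_score, entry = g$entry, mult = g$mult),
            class = "loc_result")
}

#' @export
print.loc_result <- function(x, ...) {
  cat("localization level", x$level, "| score", x$best_path_score,
      "|", x$n_configurations, "configuration(s)\n")
  print(round(x$site_probabilities, 3))
  invisible(x)
}

#' Brute-force localization oracle
#'
#' Enumerates every full assignment of the box to candidate sites explicitly,
#' scores each against the scan (same ion model as the graph), and computes
#' weights, probabilities, best assignment and level directly. Intended as an
#' independent check of [localize()]; refuses more than `max_configurations`.
#'
#' @inheritParams build_graph
#' @param weighting_base,prob_threshold As in [localize()].
#' @param max_configurations Safety cap.
#' @return A `loc_result`.
#' @export
brute_force_localize <- function(sequence, mods, box, db, scan,
                                 product_tol_ppm = 10, weighting_base = 10,
                                 prob_threshold = 0.75,
                                 max_configurations = 1e5) {
  g <- build_graph(sequence, mods, box, db, scan, product_tol_ppm)
  d <- length(g$entry)
  ns <- length(g$sites)
  # enumerate assignments: site -> distinct-entry index (0 = none)
  assigns <- list()
  rec <- function(si, remaining, cur) {
    if (length(assigns) > max_configurations) {
      stop("configuration count exceeds cap")
    }
    if (si > ns) {
      if (all(remaining == 0L)) assigns[[length(assigns) + 1L]] <<- cur
      return()
    }
    if (sum(remaining) > ns - si + 1L) return()  # cannot place the rest
    rec(si + 1L, remaining, c(cur, 0L))
    for (j in seq_len(d)) {
      if (remaining[j] > 0L) {
        r2 <- remaining
        r2[j] <- r2[j] - 1L
        rec(si + 1L, r2, c(cur, j))
      }
    }
  }
  rec(1L, g$mult, integer(0))
  n_config <- length(assigns)
  # score each assignment with the graph's node scores
  L <- g$L
  is_site_pos <- g$sites
  score_of <- function(a) {
    cnt <- integer(d)
    ci_per_pos <- integer(L)
    si <- 1L
    for (i in seq_len(L)) {
      if (si <= ns && is_site_pos[si] == i) {
        if (a[si] > 0L) cnt[a[si]] <- cnt[a[si]] + 1L
        si <- si + 1L
      }
      ci_per_pos[i] <- g$child_of(cnt)
    }
    list(score = sum(g$S[cbind(seq_len(L), ci_per_pos)]), ci = ci_per_pos)
  }
  scored <- lapply(assigns, score_of)
  scores <- vapply(scored, `[[`, numeric(1), "score")
  w <- weighting_base^scores
  Z <- sum(w)
  P <- matrix(0, ns, d,
              dimnames = list(paste0(substring(sequence, g$sites, g$sites),
                                     g$sites),
                              db$text[g$entry]))
  for (ai in seq_along(assigns)) {
    a <- assigns[[ai]]
    for (si in seq_len(ns)) {
      if (a[si] > 0L) P[si, a[si]] <- P[si, a[si]] + w[ai]
    }
  }
  P <- P / Z
  best_i <- which.max(scores)
  best <- assigns[[best_i]]
  assign <- stats::setNames(integer(0), character(0))
  for (si in seq_len(ns)) {
    if (best[si] > 0L) assign[rownames(P)[si]] <- g$entry[best[si]]
  }
  # site-determining ions along best assignment
  n_sd <- 0L
  if (L >= 2L && length(scan$mz)) {
    best_ci <- scored[[best_i]]$ci
    for (i in seq_len(L - 1L)) {
      feas_ci <- unique(vapply(scored, function(s) s$ci[i], integer(1)))
      if (length(feas_ci) < 2L) next
      ci <- best_ci[i]
      for (k in 1:4) {
        if (!g$matched[i, ci, k]) next
        if (any(abs(g$theo[i, feas_ci, k] - g$theo[i, ci, k]) > 1e-6)) {
          n_sd <- n_sd + 1L
        }
      }
    }
  }
  n_loc <- vapply(seq_len(d), function(j)
    min(g$mult[j], sum(P[, j] > prob_threshold)), numeric(1))
  all_loc <- sum(n_loc) >= box$n_glycans
  any_loc <- sum(n_loc) > 0
  level <- if (all_loc) {
    if (n_config == 1 || n_sd == 0L) "1b" else "1"
  } else if (any_loc) "2" else "3"
  structure(list(best_assignment = assign, best_path_score = scores[best_i],
                 site_probabilities = P, n_configurations = n_config,
                 n_site_determining = n_sd, level = level,
                 opair_score = scores[best_i], entry = g$entry, mult = g$mult),
            class = "loc_result")
}

#' Choose the best glycan box for a PSM and localize it
#'
#' Applies the oxonium filter (first scan) to every candidate box, localizes
#' each passing box on the second scan, and returns the box with the highest
#' best-path score; ties are broken by fewer glycans, then by canonical
#' composition text. When every box is filtered out the PSM keeps its total
#' glycan mass but its composition is `"unassigned"` at level 3. Site
#' evidence is only drawn from electron-based activation scans: if the
#' localization scan is collisional (HCD), c/z ions cannot be present and
#' localization falls back to process of elimination, so multi-site cases
#' report level 3.
#'
#' @param psm A `glyco_psm` from [search_pair()].
#' @param pair The originating scan pair.
#' @param db The `glycan_db`.
#' @param rules Oxonium rule list (may be empty).
#' @param params A `search_params`.
#' @return List with `box` (or `NULL`), `result` (`loc_result` or `NULL`),
#'   `filtered_out` (count of boxes removed by the oxonium filter).
#' @export
select_best_box <- function(psm, pair, db, rules, params = search_params()) {
  boxes <- psm$candidate_boxes
  if (!length(boxes)) return(list(box = NULL, result = NULL, filtered_out = 0L))
  pass <- vapply(boxes, function(b)
    oxonium_filter(pair$first, box_composition(db, b), rules,
                   params$product_tol_ppm), logical(1))
  n_filtered <- sum(!pass)
  boxes <- boxes[pass]
  if (!length(boxes)) {
    return(list(box = NULL, result = NULL, filtered_out = n_filtered))
  }
  scan2 <- if (is.null(pair$second)) pair$first else pair$second
  if (identical(scan2$activation, "HCD")) {
    # collisional scans carry no c/z ions (glycans dissociate); matching
    # against them would only pick up chance coincidences, so localization
    # proceeds without spectral evidence (elimination only)
    scan2$mz <- numeric(0)
    scan2$intensity <- numeric(0)
  }
  results <- lapply(boxes, function(b) {
    gph <- build_graph(psm$sequence, psm$mods, b, db, scan2,
                       params$product_tol_ppm)
    localize(gph, params$weighting_base, params$prob_threshold)
  })
  sc <- vapply(results, `[[`, numeric(1), "best_path_score")
  ng <- vapply(boxes, `[[`, integer(1), "n_glycans")
  txt <- vapply(boxes, function(b) box_text(db, b), character(1))
  b <- order(-sc, ng, txt)[1]
  list(box = boxes[[b]], result = results[[b]], filtered_out = n_filtered)
}
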