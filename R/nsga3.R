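## NSGA-III many-objective optimizer: Das-Dennis reference directions,
## fast nondominated sorting, ideal-point/intercept normalization,
## association by perpendicular distance, niche-preserving selection, and
## the generational loop with SBX crossover and polynomial mutation.
## Internally everything is minimization; maximization problems are
## negated at the boundary.

#' Das-Dennis simplex-lattice reference directions
#'
#' All M-dimensional nonnegative weight vectors with components that are
#' multiples of `1/p` and sum to 1: `choose(p + M - 1, M - 1)` points
#' uniformly covering the unit simplex.
#'
#' @param M Number of objectives (>= 2).
#' @param p Number of divisions along each objective (>= 1).
#' @return Matrix with `choose(p + M - 1, M - 1)` rows and `M` columns.
#' @export
das_dennis <- function(M, p) {
  stopifnot(M >= 2L, p >= 1L)
  recurse <- function(m, left) {
    if (m == 1L) return(matrix(left, 1L, 1L))
    out <- lapply(0:left, function(i)
      cbind(i, recurse(m - 1L, left - i)))
    do.call(rbind, out)
  }
  pts <- recurse(M, as.integer(p)) / p
  dimnames(pts) <- NULL
  pts
}

#' Fast nondominated sorting
#'
#' Partitions objective vectors into Pareto fronts. With
#' `maximize = TRUE` (the default, matching the accuracy objectives)
#' vector `a` dominates `b` when `a >= b` componentwise with at least one
#' strict inequality; fronts are defined recursively after removing
#' earlier fronts.
#'
#' @param objs Numeric matrix, one row per solution, one column per
#'   objective.
#' @param maximize Dominance direction.
#' @return List of integer vectors (row indices), front 1 first.
#' @export
nondominated_sort <- function(objs, maximize = TRUE) {
  objs <- as.matrix(objs)
  n <- nrow(objs)
  if (n == 0L) stop("empty objective set")
  if (maximize) objs <- -objs
  M <- ncol(objs)
  dom_count <- integer(n)          # how many solutions dominate i
  dominates <- vector("list", n)   # which solutions i dominates
  for (i in seq_len(n)) {
    cmp_le <- objs <= matrix(objs[i, ], n, M, byrow = TRUE)
    cmp_lt <- objs < matrix(objs[i, ], n, M, byrow = TRUE)
    dominators <- which(rowSums(cmp_le) == M & rowSums(cmp_lt) > 0L)
    dom_count[i] <- length(dominators)
    for (j in dominators)
      dominates[[j]] <- c(dominates[[j]], i)
  }
  fronts <- list()
  current <- which(dom_count == 0L)
  while (length(current)) {
    fronts[[length(fronts) + 1L]] <- current
    nxt <- integer(0)
    for (j in current) {
      for (i in dominates[[j]]) {
        dom_count[i] <- dom_count[i] - 1L
        if (dom_count[i] == 0L) nxt <- c(nxt, i)
      }
    }
    current <- sort(unique(nxt))
  }
  fronts
}

# Achievement scalarizing function used to pick extreme points.
asf_extreme_points <- function(objs_t) {
  M <- ncol(objs_t)
  ext <- matrix(0, M, M)
  for (m in seq_len(M)) {
    w <- rep(1e-6, M); w[m] <- 1
    asf <- apply(sweep(objs_t, 2L, w, "/"), 1L, max)
    ext[m, ] <- objs_t[which.min(asf), ]
  }
  ext
}

#' Normalize objectives and associate members to reference directions
#'
#' Translates objectives by the ideal point of the supplied fronts, scales
#' by the intercepts of the hyperplane through the extreme points
#' (achievement-scalarizing extremes; falls back to per-objective maxima
#' when the intercept system is singular or degenerate), then associates
#' every member with the reference direction minimizing the perpendicular
#' distance from the member's normalized objective vector to the ray.
#'
#' @param objs Numeric matrix of objective vectors (minimization scale).
#' @param front_indices Row indices participating in normalization
#'   (typically all fronts under consideration).
#' @param refs Reference-direction matrix from [das_dennis()].
#' @return List with `assoc` (reference index per row of `objs`), `dist`
#'   (perpendicular distance per row), and `normalized` objectives.
#' @export
normalize_and_associate <- function(objs, front_indices, refs) {
  objs <- as.matrix(objs)
  if (length(front_indices) == 0L) stop("empty front set")
  M <- ncol(objs)
  ideal <- apply(objs[front_indices, , drop = FALSE], 2L, min)
  ot <- sweep(objs, 2L, ideal)
  intercepts <- rep(NA_real_, M)
  ext <- asf_extreme_points(ot[front_indices, , drop = FALSE])
  sol <- tryCatch(solve(ext, rep(1, M)), error = function(e) NULL)
  if (!is.null(sol) && all(is.finite(sol)) && all(sol > 1e-10))
    intercepts <- 1 / sol
  bad <- !is.finite(intercepts) | intercepts < 1e-10
  if (any(bad)) {
    mx <- apply(ot[front_indices, , drop = FALSE], 2L, max)
    intercepts[bad] <- mx[bad]
  }
  intercepts[intercepts < 1e-10] <- 1
  norm_obj <- sweep(ot, 2L, intercepts, "/")
  ref_norm <- refs / sqrt(rowSums(refs^2))
  proj <- norm_obj %*% t(ref_norm)                  # n x R projections
  sq <- rowSums(norm_obj^2)
  d2 <- pmax(sweep(-proj^2, 1L, sq, "+"), 0)        # squared perp distance
  assoc <- max.col(-d2, ties.method = "first")
  dist <- sqrt(d2[cbind(seq_len(nrow(objs)), assoc)])
  list(assoc = assoc, dist = dist, normalized = norm_obj)
}

#' Niche-preserving selection on the split front
#'
#' Fills the remaining population slots from the last (split) front:
#' repeatedly take a reference direction with the minimum niche count
#' among those with unselected associates; if its count is zero pick the
#' associated member with minimal perpendicular distance, otherwise pick
#' uniformly at random among its associates; update the count and repeat.
#'
#' @param last_front Integer indices of the split-front members.
#' @param assoc Reference index associated with each member (full vector,
#'   indexed by member id).
#' @param dist Perpendicular distances (same indexing).
#' @param niche_counts Integer vector, current member count per reference
#'   direction from the already-accepted fronts.
#' @param needed Number of members to select (<= length(last_front)).
#' @return Integer vector of `needed` selected member indices.
#' @export
niching_select <- function(last_front, assoc, dist, niche_counts, needed) {
  if (needed > length(last_front))
    stop("needed exceeds the size of the last front")
  selected <- integer(0)
  avail <- last_front
  counts <- niche_counts
  while (length(selected) < needed) {
    refs_avail <- unique(assoc[avail])
    jmin <- refs_avail[counts[refs_avail] == min(counts[refs_avail])]
    if (length(jmin) > 1L) jmin <- jmin[sample.int(length(jmin), 1L)]
    members <- avail[assoc[avail] == jmin]
    pick <- if (counts[jmin] == 0L) {
      members[which.min(dist[members])]
    } else {
      members[sample.int(length(members), 1L)]
    }
    selected <- c(selected, pick)
    avail <- setdiff(avail, pick)
    counts[jmin] <- counts[jmin] + 1L
  }
  selected
}

# Simulated binary crossover on [lo, hi]^d genomes.
sbx_crossover <- function(p1, p2, eta, lo, hi, pc = 1.0) {
  d <- length(p1)
  c1 <- p1; c2 <- p2
  if (stats::runif(1) <= pc) {
    for (k in seq_len(d)) {
      if (stats::runif(1) <= 0.5 && abs(p1[k] - p2[k]) > 1e-14) {
        u <- stats::runif(1)
        beta <- if (u <= 0.5) (2 * u)^(1 / (eta + 1))
                else (1 / (2 * (1 - u)))^(1 / (eta + 1))
        c1[k] <- 0.5 * ((1 + beta) * p1[k] + (1 - beta) * p2[k])
        c2[k] <- 0.5 * ((1 - beta) * p1[k] + (1 + beta) * p2[k])
      }
    }
  }
  list(pmin(pmax(c1, lo), hi), pmin(pmax(c2, lo), hi))
}

# Polynomial mutation on [lo, hi]^d genomes.
poly_mutation <- function(x, eta, lo, hi, pm) {
  d <- length(x)
  for (k in seq_len(d)) {
    if (stats::runif(1) <= pm) {
      u <- stats::runif(1)
      span <- hi - lo
      delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1
               else 1 - (2 * (1 - u))^(1 / (eta + 1))
      x[k] <- min(max(x[k] + delta * span, lo), hi)
    }
  }
  x
}

#' Run the NSGA-III generational loop
#'
#' Standard workflow: initialize a population of real-coded genomes in
#' `[lower, upper]^d`, then per generation create offspring by SBX
#' crossover and polynomial mutation, merge parents and offspring,
#' nondominated-sort the merged pool, accept whole fronts while they fit,
#' and fill the remainder from the split front by reference-direction
#' niching ([normalize_and_associate()] + [niching_select()]). An archive
#' of all nondominated solutions encountered is maintained and returned.
#' Deterministic for a fixed `seed`.
#'
#' @param evaluate Function `genome -> numeric objective vector` (pure).
#' @param n_var Genome length.
#' @param n_obj Number of objectives.
#' @param config List overriding any of: `pop_size` (92), `generations`
#'   (50), `divisions_p` (6), `sbx_eta` (30), `mutation_eta` (20),
#'   `mutation_rate` (1/n_var), `seed` (1).
#' @param maximize Objective direction (default `TRUE`).
#' @param lower,upper Genome box bounds.
#' @param init Optional matrix of genomes seeded into the initial
#'   population (rows; truncated to `pop_size`).
#' @return List of class `nsga3_result`: `pop` (genomes), `objs`
#'   (objective vectors, caller's direction), `archive_pop`,
#'   `archive_objs`, `log` (per-generation front-1 size and best of each
#'   objective), and the effective `config`.
#' @export
nsga3_evolve <- function(evaluate, n_var, n_obj, config = list(),
                         maximize = TRUE, lower = 0, upper = 1,
                         init = NULL) {
  cfg <- utils::modifyList(
    list(pop_size = 92L, generations = 50L, divisions_p = 6L,
         sbx_eta = 30, mutation_eta = 20, mutation_rate = NA_real_,
         seed = 1L), config)
  if (is.na(cfg$mutation_rate)) cfg$mutation_rate <- 1 / n_var
  N <- as.integer(cfg$pop_size)
  refs <- das_dennis(n_obj, cfg$divisions_p)
  if (N < nrow(refs))
    warning(sprintf("pop_size (%d) below the number of reference points (%d)",
                    N, nrow(refs)))
  old_seed <- sub_seed(cfg$seed, 401L)
  on.exit(restore_seed(old_seed))
  pop <- matrix(stats::runif(N * n_var, lower, upper), N, n_var)
  if (!is.null(init)) {
    init <- as.matrix(init)
    k <- min(nrow(init), N)
    pop[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
  }
  eval_pop <- function(P) t(apply(P, 1L, function(g) {
    v <- evaluate(g)
    if (length(v) != n_obj || any(!is.finite(v)))
      stop("evaluate() returned an invalid objective vector for genome [",
           paste(signif(g, 3), collapse = ", "), "]")
    v
  }))
  objs <- eval_pop(pop)                 # caller's direction
  arch_pop <- NULL; arch_objs <- NULL
  update_archive <- function(P, Fv) {
    ap <- rbind(arch_pop, P); ao <- rbind(arch_objs, Fv)
    fr1 <- nondominated_sort(ao, maximize = maximize)[[1L]]
    # drop exact duplicates
    key <- apply(round(ap[fr1, , drop = FALSE], 12), 1L, paste, collapse = ",")
    keep <- fr1[!duplicated(key)]
    arch_pop <<- ap[keep, , drop = FALSE]
    arch_objs <<- ao[keep, , drop = FALSE]
  }
  update_archive(pop, objs)
  logs <- vector("list", cfg$generations)
  for (gen in seq_len(cfg$generations)) {
    # offspring by random pairing + SBX + polynomial mutation
    perm <- sample.int(N)
    off <- matrix(0, N, n_var)
    for (i in seq(1L, N - 1L, by = 2L)) {
      ch <- sbx_crossover(pop[perm[i], ], pop[perm[i + 1L], ],
                          cfg$sbx_eta, lower, upper)
      off[i, ] <- poly_mutation(ch[[1L]], cfg$mutation_eta, lower, upper,
                                cfg$mutation_rate)
      off[i + 1L, ] <- poly_mutation(ch[[2L]], cfg$mutation_eta, lower,
                                     upper, cfg$mutation_rate)
    }
    if (N %% 2L == 1L)
      off[N, ] <- poly_mutation(pop[perm[N], ], cfg$mutation_eta, lower,
                                upper, cfg$mutation_rate)
    off_objs <- eval_pop(off)
    merged <- rbind(pop, off)
    merged_objs <- rbind(objs, off_objs)
    min_objs <- if (maximize) -merged_objs else merged_objs
    fronts <- nondominated_sort(merged_objs, maximize = maximize)
    take <- integer(0); fi <- 0L
    while (fi < length(fronts) &&
           length(take) + length(fronts[[fi + 1L]]) <= N) {
      fi <- fi + 1L
      take <- c(take, fronts[[fi]])
    }
    if (length(take) < N) {
      split <- fronts[[fi + 1L]]
      considered <- c(take, split)
      na <- normalize_and_associate(min_objs, considered, refs)
      counts <- tabulate(na$assoc[take], nbins = nrow(refs))
      sel <- niching_select(split, na$assoc, na$dist, counts,
                            N - length(take))
      take <- c(take, sel)
    }
    pop <- merged[take, , drop = FALSE]
    objs <- merged_objs[take, , drop = FALSE]
    update_archive(off, off_objs)
    best <- if (maximize) apply(objs, 2L, max) else apply(objs, 2L, min)
    logs[[gen]] <- c(gen = gen, front1 = length(fronts[[1L]]),
                     stats::setNames(best, paste0("best_F", seq_len(n_obj))))
  }
  structure(list(pop = pop, objs = objs, archive_pop = arch_pop,
                 archive_objs = arch_objs,
                 log = as.data.frame(do.call(rbind, logs)),
                 config = cfg),
            class = "nsga3_result")
}

#' @export
print.nsga3_result <- function(x, ...) {
  cat(sprintf("<nsga3_result: pop %d, archive %d, %d generation(s)>\n",
              nrow(x$pop), nrow(x$archive_pop), nrow(x$log)))
  invisible(x)
}

#' Write the per-generation optimizer log as delimited text
#'
#' @param result An `nsga3_result` from [nsga3_evolve()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_nsga3_log <- function(result, path) {
  utils::write.table(result$log, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
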