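#' Cluster mutation trajectories into genotype cohorts
#'
#' Mutations residing on the same genetic background share a frequency
#' trajectory (up to sampling noise), so cohorts are recovered by clustering
#' trajectories. The distance between two mutations is the mean absolute
#' frequency difference over the days at which at least one of the pair
#' exceeds `detection_floor`; pairs with no such day never join. Clusters are
#' the connected components of the graph joining pairs with distance at most
#' `cutoff` (single-linkage agglomeration cut at `cutoff`), which makes the
#' result invariant to row order. A looser cutoff groups more mutations per
#' genotype; values of 0.1-0.2 are typical at sequencing depths of several
#' hundred reads.
#'
#' @param table A [build_trajectories()] table with at least two days.
#' @param cutoff Maximum mean absolute frequency difference for two
#'   trajectories to be linked (default 0.1).
#' @param detection_floor Frequency below which a day is treated as
#'   undetected for the distance computation (default 0).
#' @return An object of class `genotype_clusters`: a list with `members`
#'   (named list: genotype id -> mutation ids), `trajectory` (genotype x day
#'   matrix of unweighted member-mean frequencies), `days`,
#'   `first_detected_day` (named vector) and `detection_floor`. Genotype ids
#'   are assigned in order of first detection, ties broken by descending
#'   maximum frequency then by lowest member mutation id.
#' @export
cluster_genotypes <- function(table, cutoff = 0.1, detection_floor = 0) {
  stopifnot(inherits(table, "trajectory_table"))
  n <- nrow(table$freq)
  if (n < 1) abort("trajectory table has no mutations")
  if (length(table$days) < 2)
    abort("at least two days are required to cluster trajectories")
  f <- table$freq

  # pairwise mean |f_i - f_j| over days where either trajectory is detected
  comp <- seq_len(n)  # union-find forest
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        use <- f[i, ] > detection_floor | f[j, ] > detection_floor
        if (!any(use)) next
        d <- mean(abs(f[i, use] - f[j, use]))
        if (d <= cutoff) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)

  traj <- t(vapply(groups, function(idx) colMeans(f[idx, , drop = FALSE]),
                   numeric(ncol(f))))
  first_day <- vapply(seq_along(groups), function(k) {
    det <- which(traj[k, ] > detection_floor)
    if (length(det) == 0) max(table$days) else table$days[det[1]]
  }, numeric(1))
  max_freq <- apply(traj, 1, max)
  lowest_member <- vapply(groups, min, integer(1))
  ord <- order(first_day, -max_freq, lowest_member)

  ids <- sprintf("G%d", seq_along(groups))
  members <- setNames(lapply(groups[ord], function(idx) rownames(f)[idx]), ids)
  traj <- traj[ord, , drop = FALSE]
  rownames(traj) <- ids
  structure(list(members = members, trajectory = traj, days = table$days,
                 first_detected_day = setNames(first_day[ord], ids),
                 detection_floor = detection_floor,
                 population = table$population),
            class = "genotype_clusters")
}

#' @export
print.genotype_clusters <- function(x, ...) {
  cat(sprintf("<genotype_clusters> %d genotypes from %d mutations over %d days\n",
              length(x$members), sum(lengths(x$members)), length(x$days)))
  invisible(x)
}

#' Infer a nested genealogy over genotype cohorts
#'
#' A derived genotype arises within an existing background, so its frequency
#' can never exceed its parent's, and the summed frequencies of a genotype's
#' direct children cannot exceed its own. Genotypes are placed in order of
#' first detection (ties: descending maximum frequency), and each is attached
#' to the already-placed candidate parent that satisfies both nesting
#' constraints (within `nest_tolerance`, which absorbs binomial sampling
#' noise) while minimising the summed area between parent and child
#' trajectories; if no candidate qualifies the genotype is a root. Roots must
#' jointly respect total frequency 1 within tolerance.
#'
#' @param clusters A [cluster_genotypes()] object.
#' @param nest_tolerance Allowed violation of the nesting inequalities
#'   (default 0.05).
#' @param strict With `strict = TRUE` (default) an error is raised when a
#'   genotype can neither be nested under any placed genotype nor added as a
#'   root without pushing the summed root frequencies past 1 + tolerance.
#'   With `strict = FALSE` such a genotype is attached wherever the total
#'   constraint violation is smallest (reported via a warning), which keeps
#'   genealogies buildable on noisy data.
#' @return An object of class `genealogy_forest`: the clusters plus `parent`
#'   (named vector: genotype -> parent genotype or `"ROOT"`) and
#'   `nest_tolerance`.
#' @export
infer_genealogy <- function(clusters, nest_tolerance = 0.05, strict = TRUE) {
  stopifnot(inherits(clusters, "genotype_clusters"))
  traj <- clusters$trajectory
  ids <- rownames(traj)
  ord <- order(clusters$first_detected_day, -apply(traj, 1, max),
               seq_along(ids))
  parent <- setNames(rep(NA_character_, length(ids)), ids)

  children_sum <- matrix(0, nrow = length(ids), ncol = ncol(traj),
                         dimnames = dimnames(traj))
  root_sum <- numeric(ncol(traj))

  for (k in ord) {
    id <- ids[k]
    f_child <- traj[k, ]
    placed <- ids[!is.na(parent)]
    valid <- placed[vapply(placed, function(p) {
      all(traj[p, ] >= f_child - nest_tolerance) &&
        all(children_sum[p, ] + f_child <= traj[p, ] + nest_tolerance)
    }, logical(1))]
    if (length(valid) > 0) {
      area <- vapply(valid, function(p) sum(traj[p, ] - f_child), numeric(1))
      best <- valid[order(area, match(valid, ids))][1]
      parent[id] <- best
      children_sum[best, ] <- children_sum[best, ] + f_child
    } else if (all(root_sum + f_child <= 1 + nest_tolerance)) {
      parent[id] <- "ROOT"
      root_sum <- root_sum + f_child
    } else if (strict) {
      abort("inconsistent genealogy: root genotype frequencies exceed 1 (",
            id, ")")
    } else {
      # least-violating attachment: candidate parents are ROOT and every
      # placed genotype; violation = nesting excess + children-sum excess
      violation <- c(ROOT = sum(pmax(0, root_sum + f_child - 1)),
                     vapply(placed, function(p) {
                       sum(pmax(0, f_child - traj[p, ])) +
                         sum(pmax(0, children_sum[p, ] + f_child - traj[p, ]))
                     }, numeric(1)))
      best <- names(violation)[order(violation,
                                     match(names(violation), c("ROOT", ids)))][1]
      warning("genealogy inconsistency: ", id, " attached to ", best,
              " with constraint violation ", signif(min(violation), 3),
              call. = FALSE)
      parent[id] <- best
      if (best == "ROOT") root_sum <- root_sum + f_child
      else children_sum[best, ] <- children_sum[best, ] + f_child
    }
  }
  structure(c(unclass(clusters),
              list(parent = parent, nest_tolerance = nest_tolerance)),
            class = c("genealogy_forest", "genotype_clusters"))
}

# ancestors of a genotype, nearest first (excluding ROOT)
ancestry_path <- function(forest, id) {
  path <- character(0)
  p <- forest$parent[[id]]
  while (p != "ROOT") {
    path <- c(path, p)
    p <- forest$parent[[p]]
  }
  path
}

#' Detect genotype fixation events
#'
#' A genotype fixes at the first sampled day its trajectory reaches
#' `fixed_threshold`, provided it never drops below
#' `fixed_threshold - nest_tolerance` at any later sampled day (sampled
#' frequencies rarely hit 1.0 exactly at finite depth, hence the threshold
#' below 1). A genotype that crosses the threshold but later collapses is
#' not fixed, even if it crosses again. Each event sweeps the genotype's own member mutations plus the
#' members of all its ancestors that were not already swept by an earlier
#' event.
#'
#' @param forest An [infer_genealogy()] forest.
#' @param fixed_threshold Frequency treated as fixation (default 0.97).
#' @return Data frame with columns `genotype`, `fixation_day`,
#'   `n_mutations_swept`, ordered by fixation day.
#' @export
detect_fixations <- function(forest, fixed_threshold = 0.97) {
  stopifnot(inherits(forest, "genealogy_forest"))
  traj <- forest$trajectory
  tol <- forest$nest_tolerance
  events <- list()
  for (id in rownames(traj)) {
    f <- traj[id, ]
    first <- which(f >= fixed_threshold)[1]
    if (!is.na(first) &&
        all(f[seq_along(f) >= first] >= fixed_threshold - tol)) {
      events[[id]] <- data.frame(genotype = id,
                                 fixation_day = forest$days[first],
                                 stringsAsFactors = FALSE)
    }
  }
  if (length(events) == 0) {
    return(data.frame(genotype = character(0), fixation_day = numeric(0),
                      n_mutations_swept = integer(0)))
  }
  events <- do.call(rbind, events)
  events <- events[order(events$fixation_day, events$genotype), , drop = FALSE]

  swept <- character(0)
  events$n_mutations_swept <- NA_integer_
  for (r in seq_len(nrow(events))) {
    lineage <- c(events$genotype[r], ancestry_path(forest, events$genotype[r]))
    new_members <- setdiff(unlist(forest$members[lineage]), swept)
    events$n_mutations_swept[r] <- length(new_members)
    swept <- c(swept, new_members)
  }
  rownames(events) <- NULL
  events
}

#' Build a Muller table from a genealogy forest
#'
#' Converts inclusive genotype trajectories into the exclusive (per-shade)
#' frequencies drawn in a Muller plot: each genotype's exclusive frequency is
#' its own trajectory minus the summed trajectories of its direct children
#' (clamped at 0), and a synthetic `background` row absorbs the frequency not
#' explained by any root genotype. Rows are emitted in genealogical preorder,
#' so at every day the frequencies sum to 1.
#'
#' @param forest An [infer_genealogy()] forest.
#' @param strict With `strict = TRUE` (default) an error is raised when the
#'   total mass removed by clamping exceeds the forest's nesting tolerance at
#'   any day; with `strict = FALSE` the inconsistency is reported as a
#'   warning and the day is renormalised (useful on noisy data where many
#'   individually-tolerable violations add up).
#' @return Data frame with columns `day`, `genotype`, `parent`, `frequency`
#'   (class `muller_table`). The total mass removed by clamping at each day
#'   is available as `attr(x, "clamp_loss")`.
#' @export
muller_table <- function(forest, strict = TRUE) {
  stopifnot(inherits(forest, "genealogy_forest"))
  traj <- forest$trajectory
  ids <- rownames(traj)
  kids <- split(ids, factor(forest$parent[ids], levels = c("ROOT", ids)))

  exclusive <- traj
  clamp_loss <- numeric(ncol(traj))
  for (id in ids) {
    ch <- kids[[id]]
    if (length(ch) > 0) {
      resid <- traj[id, ] - colSums(traj[ch, , drop = FALSE])
      clamp_loss <- clamp_loss + pmax(0, -resid)
      exclusive[id, ] <- pmax(0, resid)
    }
  }
  roots <- kids[["ROOT"]]
  background <- pmax(0, 1 - colSums(traj[roots, , drop = FALSE]))
  clamp_loss <- clamp_loss +
    pmax(0, colSums(traj[roots, , drop = FALSE]) - 1)
  if (any(clamp_loss > forest$nest_tolerance)) {
    msg <- paste0("inconsistent Muller table: clamping removes more mass ",
                  "than the nesting tolerance at day(s) ",
                  paste(forest$days[clamp_loss > forest$nest_tolerance],
                        collapse = ", "))
    if (strict) abort(msg) else warning(msg, call. = FALSE)
  }

  # genealogical preorder
  preorder <- character(0)
  visit <- function(id) {
    preorder <<- c(preorder, id)
    for (ch in kids[[id]]) visit(ch)
  }
  for (r in roots) visit(r)

  total <- background + colSums(exclusive, na.rm = TRUE)
  rows <- data.frame(
    day = rep(forest$days, times = length(preorder) + 1),
    genotype = rep(c("background", preorder), each = length(forest$days)),
    parent = rep(c("ROOT", forest$parent[preorder]), each = length(forest$days)),
    frequency = c(background / total,
                  as.vector(t(exclusive[preorder, , drop = FALSE] / rep(total, each = length(preorder))))),
    stringsAsFactors = FALSE)
  structure(rows, clamp_loss = setNames(clamp_loss, paste0("day", forest$days)),
            class = c("muller_table", "data.frame"))
}

#' Count genotypes present at a day
#'
#' @param clusters A [cluster_genotypes()] object (or forest).
#' @param day One of the sampled days.
#' @param detection_floor Presence threshold; defaults to the value used at
#'   clustering time.
#' @return Number of genotypes with trajectory above the floor at `day`.
#' @export
genotype_richness <- function(clusters, day,
                              detection_floor = clusters$detection_floor) {
  j <- match(day, clusters$days)
  if (is.na(j)) abort("day ", day, " was not sampled")
  sum(clusters$trajectory[, j] > detection_floor)
}

#' Export genotype tables in ggmuller-compatible layout
#'
#' @param forest An [infer_genealogy()] forest.
#' @param dir Output directory.
#' @return Invisibly, the paths written: a population table
#'   (Generation, Identity, Frequency) and an adjacency table
#'   (Parent, Identity).
#' @export
write_muller_tables <- function(forest, dir, strict = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mt <- muller_table(forest, strict = strict)
  pop <- data.frame(Generation = mt$day, Identity = mt$genotype,
                    Frequency = mt$frequency)
  edges <- unique(data.frame(Parent = mt$parent, Identity = mt$genotype))
  edges <- edges[edges$Identity != "background", , drop = FALSE]
  p1 <- file.path(dir, "muller_population.csv")
  p2 <- file.path(dir, "muller_edges.csv")
  utils::write.csv(pop, p1, row.names = FALSE, quote = FALSE)
  utils::write.csv(edges, p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}
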