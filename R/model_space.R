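## Combinatorial model space of engineered communities.
##
## Each strain optionally expresses one QS signal (A1/A2) and one bacteriocin
## (B1-B3), and may be sensitive to one bacteriocin. Each bacteriocin present
## in a system carries a system-level regulator (which QS controls it) and a
## regulation mode (induced/repressed). A model is an unordered set of three
## distinct strains plus the per-bacteriocin regulation assignment; part
## labels are canonicalised by first-use renumbering, so relabelling B/A
## species does not create new models.
##
## Internal row encoding (integer vector, 15 slots):
##   s{k}_sens, s{k}_qs, s{k}_bact  for k = 1..3   (0 = none)
##   reg_z, mode_z                  for z = 1..3   (0 when B_z absent)

.ms_cols <- c(t(outer(paste0("s", 1:3), c("sens", "qs", "bact"),
                      paste, sep = "_")),
              paste0(rep(c("reg", "mode"), 3), rep(1:3, each = 2)))

#' Enumerate unique engineered strain configurations
#'
#' All combinations of sensitivity (none/B1/B2/B3), QS expression
#' (none/A1/A2), bacteriocin expression (none/B1/B2/B3) and regulation mode
#' (induced/repressed), with the mode normalised to a single sentinel when
#' no bacteriocin is expressed (it is meaningless there).
#'
#' @return data frame with columns `sens`, `qs`, `bact` (integer codes,
#'   0 = none) and `mode` (0 = induced, 1 = repressed, 0 when `bact` = 0).
#' @export
enumerate_strain_configs <- function() {
  g <- expand.grid(mode = 0:1, bact = 0:3, qs = 0:2, sens = 0:3)
  g$mode[g$bact == 0] <- 0L
  g <- unique(g[, c("sens", "qs", "bact", "mode")])
  rownames(g) <- NULL
  g[order(g$sens, g$qs, g$bact, g$mode), , drop = FALSE]
}

#' Enumerate the raw (unpruned) community model space
#'
#' Builds every unordered combination of strain configurations for
#' `n_strains` strains together with every per-bacteriocin regulation
#' assignment (regulator in \{A1, A2\}, mode in \{induced, repressed\}).
#' The result still contains models violating the redundancy rules; apply
#' [prune_models()] to obtain the working space.
#'
#' @param n_strains number of strains (1-3 supported; the calibrated space
#'   uses 3).
#' @return a `model_space` (list with `models` integer matrix, `convention`,
#'   and `pruned = FALSE`).
#' @export
enumerate_models <- function(n_strains = 3) {
  if (!n_strains %in% 1:3) stop("n_strains must be 1, 2 or 3")
  cfg <- expand.grid(sens = 0:3, qs = 0:2, bact = 0:3)
  nc <- nrow(cfg)  # 48
  idx <- utils::combn(nc + n_strains - 1, n_strains)  # multisets via stars/bars
  idx <- idx - (seq_len(n_strains) - 1)               # combinations with repetition

  smat <- matrix(0L, ncol(idx), 3 * n_strains)
  for (k in seq_len(n_strains)) {
    ck <- cfg[idx[k, ], ]
    smat[, (k - 1) * 3 + 1:3] <- cbind(ck$sens, ck$qs, ck$bact)
  }
  bact_cols <- seq(3, 3 * n_strains, by = 3)
  present <- vapply(1:3, function(z)
    rowSums(smat[, bact_cols, drop = FALSE] == z) > 0, logical(nrow(smat)))
  nb <- rowSums(present)

  ## expand each triple by 4^nb regulation assignments of its present bacteriocins
  reps <- as.integer(4^nb)
  base <- smat[rep(seq_len(nrow(smat)), reps), , drop = FALSE]
  assign_mat <- matrix(0L, nrow(base), 6)
  variant <- sequence(reps) - 1L   # 0 .. 4^nb - 1 within each triple
  pres_rep <- present[rep(seq_len(nrow(smat)), reps), , drop = FALSE]
  rank_mat <- pres_rep + 0L
  if (ncol(rank_mat) > 1)
    for (j in 2:ncol(rank_mat)) rank_mat[, j] <- rank_mat[, j] + rank_mat[, j - 1]
  for (z in 1:3) {
    has <- pres_rep[, z]
    digit <- (variant %/% 4^(rank_mat[, z] - 1)) %% 4
    assign_mat[has, 2 * z - 1] <- 1L + (digit[has] %/% 2L)  # regulator 1/2
    assign_mat[has, 2 * z]     <- as.integer(digit[has] %% 2L)  # mode 0/1
  }
  pad <- matrix(0L, nrow(base), 9 - 3 * n_strains)
  models <- cbind(base, pad, assign_mat)
  storage.mode(models) <- "integer"
  colnames(models) <- .ms_cols
  structure(list(models = models, n_strains = as.integer(n_strains),
                 pruned = FALSE,
                 convention = .enumeration_convention()),
            class = "model_space")
}

.enumeration_convention <- function() {
  list(triples = "unordered (strain labels interchangeable)",
       regulation = "system-level per bacteriocin: one regulator QS and one mode",
       canonicalisation = paste("bacteriocin/QS labels renumbered by first use",
                                "over lexicographically sorted strains,",
                                "iterated to a fixpoint"),
       mode_normalisation = "mode fixed to 0 when no bacteriocin is expressed",
       model_id = "row rank under lexicographic order of the canonical encoding")
}

## rule checks, vectorised over the model matrix
.rule_flags <- function(m, n_strains = 3) {
  scol <- function(k, f) m[, paste0("s", k, "_", f)]
  ks <- seq_len(n_strains)
  bact <- sapply(ks, function(k) scol(k, "bact"))
  qs   <- sapply(ks, function(k) scol(k, "qs"))
  sens <- sapply(ks, function(k) scol(k, "sens"))
  if (n_strains == 1) { bact <- cbind(bact); qs <- cbind(qs); sens <- cbind(sens) }
  present <- sapply(1:3, function(z) rowSums(bact == z) > 0)
  qs_present <- sapply(1:2, function(a) rowSums(qs == a) > 0)
  sens_present <- sapply(1:3, function(z) rowSums(sens == z) > 0)

  ## rule 1: no two strains identical in (sens, qs, bact)
  dup <- rep(FALSE, nrow(m))
  if (n_strains > 1) {
    for (i in seq_len(n_strains - 1)) for (j in seq(i + 1, n_strains)) {
      dup <- dup | (scol(i, "sens") == scol(j, "sens") &
                    scol(i, "qs") == scol(j, "qs") &
                    scol(i, "bact") == scol(j, "bact"))
    }
  }
  ## rule 2: the regulator of every present bacteriocin is present
  reg_ok <- rep(TRUE, nrow(m))
  for (z in 1:3) {
    reg <- m[, paste0("reg", z)]
    bad <- present[, z] & (reg < 1 | !qs_present[cbind(seq_len(nrow(m)),
                                                       pmax(reg, 1))])
    reg_ok <- reg_ok & !bad
  }
  ## rule 3: no sensitivity to an absent bacteriocin
  sens_ok <- rep(TRUE, nrow(m))
  for (k in ks) {
    sv <- scol(k, "sens")
    bad <- sv > 0 & !present[cbind(seq_len(nrow(m)), pmax(sv, 1))]
    sens_ok <- sens_ok & !bad
  }
  ## rule 4: every present bacteriocin has a sensitive strain
  cover_ok <- rep(TRUE, nrow(m))
  for (z in 1:3)
    cover_ok <- cover_ok & (!present[, z] | sens_present[, z])
  cbind(rule1 = !dup, rule2 = reg_ok, rule3 = sens_ok, rule4 = cover_ok)
}

## canonical first-use renumbering of one model row
.canonicalise_row <- function(row, n_strains = 3) {
  tri <- matrix(row[seq_len(3 * n_strains)], ncol = 3, byrow = TRUE)
  reg <- row[9 + c(1, 3, 5)]; mode <- row[9 + c(2, 4, 6)]
  ## strain tuples carry the mode of their expressed bacteriocin
  smode <- ifelse(tri[, 3] > 0, mode[pmax(tri[, 3], 1)], 0L)
  tri <- cbind(tri, smode)
  tri <- tri[do.call(order, as.data.frame(tri)), , drop = FALSE]
  present <- sort(unique(tri[, 3][tri[, 3] > 0]))
  for (iter in 1:10) {
    bmap <- integer(3); amap <- integer(2); nb <- 0L; na_ <- 0L
    see_b <- function(b) if (b > 0 && bmap[b] == 0) { nb <<- nb + 1L; bmap[b] <<- nb }
    see_a <- function(a) if (a > 0 && amap[a] == 0) { na_ <<- na_ + 1L; amap[a] <<- na_ }
    for (k in seq_len(nrow(tri))) {
      see_b(tri[k, 3])
      if (tri[k, 3] > 0) see_a(reg[tri[k, 3]])
      see_a(tri[k, 2])
      see_b(tri[k, 1])
    }
    map_b <- function(b) ifelse(b > 0, bmap[pmax(b, 1)], 0L)
    map_a <- function(a) ifelse(a > 0, amap[pmax(a, 1)], 0L)
    nt <- cbind(map_b(tri[, 1]), map_a(tri[, 2]), map_b(tri[, 3]), tri[, 4])
    nreg <- integer(3); nmode <- integer(3)
    for (z in present) { nreg[bmap[z]] <- amap[reg[z]]; nmode[bmap[z]] <- mode[z] }
    nt <- nt[do.call(order, as.data.frame(nt)), , drop = FALSE]
    converged <- all(nt == tri) && all(nreg == reg[1:3]) &&
      all(nmode == mode[1:3])
    tri <- nt; reg <- nreg; mode <- nmode
    present <- sort(unique(tri[, 3][tri[, 3] > 0]))
    if (converged) break
  }
  out <- integer(15)
  out[seq_len(3 * n_strains)] <- as.integer(t(tri[, 1:3, drop = FALSE]))
  out[9 + c(1, 3, 5)] <- reg[1:3]
  out[9 + c(2, 4, 6)] <- mode[1:3]
  out
}

#' Remove redundant community models
#'
#' Applies the four redundancy rules -- (1) no two identical strains,
#' (2) the regulating QS of every bacteriocin must be present, (3) no
#' sensitivity to an absent bacteriocin, (4) every bacteriocin must have a
#' sensitive strain -- then canonicalises part labels and removes duplicate
#' models. Idempotent.
#'
#' @param space a `model_space` from [enumerate_models()].
#' @return the pruned `model_space`, with `model_id` assigned by
#'   lexicographic order of the canonical encoding.
#' @export
prune_models <- function(space) {
  m <- space$models
  ns <- space$n_strains
  keep <- rowSums(.rule_flags(m, ns)) == 4
  m <- m[keep, , drop = FALSE]
  if (nrow(m)) {
    canon <- t(apply(m, 1, .canonicalise_row, n_strains = ns))
    colnames(canon) <- .ms_cols
    key <- do.call(paste, c(as.data.frame(canon), sep = "."))
    canon <- canon[!duplicated(key), , drop = FALSE]
    ord <- do.call(order, as.data.frame(canon))
    m <- canon[ord, , drop = FALSE]
  }
  rownames(m) <- NULL
  structure(list(models = m, n_strains = ns, pruned = TRUE,
                 model_id = seq_len(nrow(m)),
                 convention = space$convention),
            class = "model_space")
}

#' @export
print.model_space <- function(x, ...) {
  cat("<model_space> ", nrow(x$models), " models (", x$n_strains, " strains, ",
      if (isTRUE(x$pruned)) "pruned" else "unpruned", ")\n", sep = "")
  invisible(x)
}

#' Extract one community model from a model space
#'
#' @param space a pruned `model_space`.
#' @param model_id model index (row in the canonical ordering).
#' @return a `community_model`: list with a `strains` data frame
#'   (`sens`, `qs`, `bact`, `mode`) and a `regulators` vector (per
#'   bacteriocin label, 0 when absent).
#' @export
get_model <- function(space, model_id) {
  row <- space$models[model_id, ]
  strains <- data.frame(
    sens = row[c(1, 4, 7)][seq_len(space$n_strains)],
    qs   = row[c(2, 5, 8)][seq_len(space$n_strains)],
    bact = row[c(3, 6, 9)][seq_len(space$n_strains)])
  reg <- row[9 + c(1, 3, 5)]; mode <- row[9 + c(2, 4, 6)]
  strains$mode <- ifelse(strains$bact > 0, mode[pmax(strains$bact, 1)], 0L)
  structure(list(model_id = model_id, strains = strains,
                 regulators = reg, modes = mode),
            class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> id", x$model_id, "\n")
  print(x$strains)
  invisible(x)
}

#' Structural property summary of a community model
#'
#' Counts expressed parts and summarises regulation and interaction classes:
#' an interaction is self-limiting (SL) when a strain is killed by a
#' bacteriocin it produces, other-limiting (OL) when the killer is produced
#' by another strain.
#'
#' @param model a `community_model`.
#' @return list with `n_parts_expressed`, `n_qs`, `n_bacteriocins`,
#'   `regulation_summary` (`"positive"`, `"negative"`, `"both"` or `"none"`)
#'   and `interaction_summary` (`"SL"`, `"OL"`, `"SL+OL"` or `"none"`).
#' @export
model_properties <- function(model) {
  s <- model$strains
  present <- sort(unique(s$bact[s$bact > 0]))
  n_parts <- sum(s$qs > 0) + sum(s$bact > 0)
  n_qs <- length(unique(s$qs[s$qs > 0]))
  modes <- model$modes[present]
  reg_sum <- if (!length(present)) "none"
    else if (all(modes == 0)) "positive"
    else if (all(modes == 1)) "negative" else "both"
  sl <- ol <- FALSE
  for (z in present) {
    producers <- which(s$bact == z)
    victims <- which(s$sens == z)
    for (v in victims) {
      if (v %in% producers) sl <- TRUE
      if (length(setdiff(producers, v)) > 0) ol <- TRUE
    }
  }
  inter <- if (sl && ol) "SL+OL" else if (sl) "SL" else if (ol) "OL" else "none"
  list(n_parts_expressed = n_parts, n_qs = n_qs,
       n_bacteriocins = length(present),
       regulation_summary = reg_sum, interaction_summary = inter)
}

#' Build the ODE structure of a community model
#'
#' Translates a `community_model` into the `community_structure` consumed by
#' the simulator: present bacteriocins/QS are renumbered consecutively, and
#' expression/sensitivity/regulation are expressed as index matrices. The
#' resulting state dimension is `n_strains + 1 + n_bacteriocins + n_qs`.
#'
#' @param model a `community_model`.
#' @return a `community_structure`.
#' @export
build_equation_structure <- function(model) {
  s <- model$strains
  nN <- nrow(s)
  bact_present <- sort(unique(s$bact[s$bact > 0]))
  qs_present <- sort(unique(c(s$qs[s$qs > 0], model$regulators[bact_present])))
  qs_present <- qs_present[qs_present > 0]
  bmap <- integer(3); bmap[bact_present] <- seq_along(bact_present)
  amap <- integer(2); amap[qs_present] <- seq_along(qs_present)
  nB <- length(bact_present); nA <- length(qs_present)
  if (nB > 0 && nA == 0)
    stop("model has a bacteriocin but no QS: cannot build equations")
  EB <- matrix(0, nN, max(nB, 1))[, seq_len(nB), drop = FALSE]
  EA <- matrix(0, nN, max(nA, 1))[, seq_len(nA), drop = FALSE]
  for (k in seq_len(nN)) {
    if (s$bact[k] > 0) EB[k, bmap[s$bact[k]]] <- 1
    if (s$qs[k] > 0) EA[k, amap[s$qs[k]]] <- 1
  }
  sens <- ifelse(s$sens > 0, bmap[pmax(s$sens, 1)], 0L)
  reg <- as.integer(amap[pmax(model$regulators[bact_present], 1)])
  mode <- as.integer(model$modes[bact_present])
  structure(list(n_strains = nN, n_bact = nB, n_qs = nA,
                 sens = as.integer(sens), EB = EB, EA = EA,
                 reg = reg, mode = mode),
            class = "community_structure")
}

## canonical key of an arbitrary structure, used for structural lookup
.structure_key <- function(st) {
  row <- integer(15)
  s <- data.frame(sens = st$sens, qs = 0L, bact = 0L)
  for (k in seq_len(st$n_strains)) {
    b <- which(st$EB[k, ] > 0); a <- which(st$EA[k, ] > 0)
    s$bact[k] <- if (length(b)) b else 0L
    s$qs[k] <- if (length(a)) a else 0L
  }
  row[seq_len(3 * st$n_strains)] <- as.integer(t(as.matrix(s)))
  for (z in seq_len(st$n_bact)) {
    row[9 + 2 * z - 1] <- st$reg[z]
    row[9 + 2 * z] <- st$mode[z]
  }
  paste(.canonicalise_row(row, st$n_strains), collapse = ".")
}

#' Locate a model in the space by structural identity
#'
#' @param space a pruned `model_space`.
#' @param structure a `community_structure` (e.g. [focal_structure()]).
#' @return the matching `model_id`, or `NA` if absent.
#' @export
find_model <- function(space, structure) {
  key <- .structure_key(structure)
  keys <- apply(space$models, 1, function(r)
    paste(.canonicalise_row(r, space$n_strains), collapse = "."))
  id <- which(keys == key)
  if (length(id)) id[1] else NA_integer_
}

#' Write a model space to CSV (plus a JSON convention sidecar)
#'
#' @param space a `model_space`.
#' @param file CSV path; the sidecar is written to `<file>.json`.
#' @export
write_model_space <- function(space, file) {
  df <- as.data.frame(space$models)
  df <- cbind(model_id = seq_len(nrow(df)), df)
  utils::write.csv(df, file, row.names = FALSE)
  jsonlite::write_json(
    list(n_strains = space$n_strains, pruned = space$pruned,
         convention = space$convention),
    paste0(file, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

#' Read a model space written by [write_model_space()]
#'
#' @param file CSV path.
#' @return a `model_space`.
#' @export
read_model_space <- function(file) {
  df <- utils::read.csv(file)
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  m <- as.matrix(df[, -1]); storage.mode(m) <- "integer"
  colnames(m) <- .ms_cols
  structure(list(models = m, n_strains = as.integer(meta$n_strains),
                 pruned = meta$pruned, model_id = df$model_id,
                 convention = meta$convention),
            class = "model_space")
}

#' The calibrated three-strain model space
#'
#' Enumerates and prunes the full three-strain space under the package's
#' canonical convention. The result is deterministic.
#'
#' @return a pruned `model_space`.
#' @export
three_strain_space <- function() {
  prune_models(enumerate_models(3))
}
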