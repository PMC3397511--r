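# The packaged 71-compound thiourea MK-2 inhibitor series: printed activity
# table with train/test flags, and a series definition (scaffold templates +
# R-group fragments) that rebuilds 3D structures from SMILES.
#
# The activity values, model predictions and the asterisk-marked test split
# are the printed ones. The 2D structures are a documented reconstruction
# from R-group names around an aminopyrazine-thiourea-benzoxazolone core;
# compounds 65-71 carry figure-only substituents and are flagged
# confidence="low" in the series table.

#' The packaged thiourea activity table
#'
#' @return data.frame with columns `compound_id`, `pIC50` (experimental, in
#'   -log10 molar units), `set_label` (`train`/`test`, 53 + 18), and the
#'   model-predicted activities `pred_comfa`, `pred_comsia`.
#' @export
thiourea_activity <- function() {
  act <- read.csv(qsar3d_file("thiourea_activity.csv"),
                  colClasses = c(compound_id = "character"))
  stopifnot(nrow(act) == 71L,
            all(act$set_label %in% c("train", "test")),
            all(is.finite(act$pIC50)))
  act
}

#' The packaged thiourea series definition
#'
#' @return list with `compounds` (one row per compound: scaffold id, R-group
#'   names and SMILES fragments, confidence flag) and `scaffolds`
#'   (scaffold id -> SMILES template with `{R1}`/`{R2}` attachment tokens).
#' @export
thiourea_series <- function() {
  compounds <- read.csv(qsar3d_file("thiourea_series.csv"),
                        colClasses = "character")
  scaffolds <- read.csv(qsar3d_file("thiourea_scaffolds.csv"),
                        colClasses = "character")
  stopifnot(nrow(compounds) == 71L,
            all(compounds$scaffold_id %in% scaffolds$scaffold_id))
  list(compounds = compounds, scaffolds = scaffolds)
}

#' Common-scaffold SMARTS of the thiourea series
#'
#' The aminopyrazine + thiourea linker shared by all 71 compounds, used as
#' the default alignment substructure (the template is compound 70).
#' @return SMARTS string.
#' @export
thiourea_scaffold_smarts <- function() "Nc1nccnc1NC(=S)N"

#' Assemble a compound SMILES from the series definition
#'
#' R-group fragments are spliced into the scaffold template at the `{R1}` and
#' `{R2}` tokens; an empty fragment (hydrogen) removes the attachment
#' parentheses.
#'
#' @param template scaffold SMILES with `{R1}`/`{R2}` tokens.
#' @param r1,r2 substituent SMILES fragments (`""` for H).
#' @return SMILES string.
#' @export
assemble_smiles <- function(template, r1 = "", r2 = "") {
  s <- gsub("{R1}", r1, template, fixed = TRUE)
  s <- gsub("{R2}", r2, s, fixed = TRUE)
  gsub("()", "", s, fixed = TRUE)
}

#' Build the packaged thiourea series in 3D
#'
#' Resolves every compound row of the series definition to a SMILES, embeds a
#' 3D conformer (distance geometry + force-field minimization) and assigns
#' Gasteiger charges through the RDKit bridge, and pairs the set with the
#' printed activity table.
#'
#' @param defn series definition, by default [thiourea_series()].
#' @param ids optional subset of compound ids to build (useful for fast
#'   integration tests; the full build embeds 71 conformers).
#' @param seed conformer-embedding seed.
#' @return list with `set` (a `qsar_molecule_set`) and `activity` (the
#'   matching rows of [thiourea_activity()]).
#' @export
build_thiourea_series <- function(defn = thiourea_series(), ids = NULL,
                                  seed = 20120608L) {
  comp <- defn$compounds
  if (!is.null(ids)) {
    ids <- as.character(ids)
    missing <- setdiff(ids, comp$compound_id)
    if (length(missing)) stop("unknown compound ids: ", paste(missing, collapse = ", "))
    comp <- comp[match(ids, comp$compound_id), ]
  }
  tmpl <- setNames(defn$scaffolds$template, defn$scaffolds$scaffold_id)
  records <- lapply(seq_len(nrow(comp)), function(i) {
    row <- comp[i, ]
    if (is.na(tmpl[row$scaffold_id]))
      stop("compound ", row$compound_id, ": unknown scaffold ", row$scaffold_id)
    list(smiles = assemble_smiles(tmpl[[row$scaffold_id]],
                                  row$r1_smiles, row$r2_smiles),
         id = row$compound_id)
  })
  set <- embed_smiles(records, seed = seed)
  act <- thiourea_activity()
  act <- act[match(comp$compound_id, act$compound_id), ]
  list(set = set, activity = act)
}

#' Split an activity table into training and test sets
#'
#' `printed` mode returns the packaged asterisk-marked split (53 train / 18
#' test for the fixture). `rational` mode spreads the test set over the first
#' two principal components of a supplied descriptor matrix: descriptor space
#' is scanned with k-means-style far-point sampling so test compounds cover
#' the chemical space, with ties broken by ascending compound id so that
#' duplicated rows stay in one set.
#'
#' @param activity data.frame with `compound_id` and, for printed mode, a
#'   `set_label` column.
#' @param mode `"printed"` or `"rational"`.
#' @param fraction test fraction for rational mode (default 18/71).
#' @param descriptors numeric matrix (rows = compounds, in activity-table
#'   order) for rational mode.
#' @param seed random seed for rational mode.
#' @return list with character vectors `train` and `test` (compound ids).
#' @export
split_dataset <- function(activity, mode = c("printed", "rational"),
                          fraction = 18 / 71, descriptors = NULL, seed = 1L) {
  mode <- match.arg(mode)
  ids <- as.character(activity$compound_id)
  if (mode == "printed") {
    if (is.null(activity$set_label) || anyNA(activity$set_label))
      stop("printed mode requires a complete set_label column")
    return(list(train = ids[activity$set_label == "train"],
                test  = ids[activity$set_label == "test"]))
  }
  if (length(ids) < 2L) stop("rational mode needs at least 2 compounds")
  if (is.null(descriptors)) stop("rational mode needs a descriptor matrix")
  descriptors <- as.matrix(descriptors)
  stopifnot(nrow(descriptors) == length(ids))
  n_test <- floor(fraction * length(ids))
  if (n_test == 0L) return(list(train = ids, test = character()))
  keep <- apply(descriptors, 2, function(col) sd(col) > 0)
  pc <- if (any(keep)) {
    sc <- scale(descriptors[, keep, drop = FALSE])
    pr <- stats::prcomp(sc, center = FALSE, scale. = FALSE)
    pr$x[, seq_len(min(2L, ncol(pr$x))), drop = FALSE]
  } else {
    matrix(0, length(ids), 1L)
  }
  # duplicates must not straddle the split: operate on unique descriptor rows
  key <- apply(round(pc, 10), 1, paste, collapse = "|")
  ord <- order(key, ids)                     # ascending-id tie-break
  rep_idx <- ord[!duplicated(key[ord])]      # representative = lowest id
  groups <- split(seq_along(ids), key)
  set.seed(seed)
  sel <- farthest_point_sample(pc[rep_idx, , drop = FALSE],
                               min(n_test, length(rep_idx)))
  test_keys <- key[rep_idx[sel]]
  test <- sort(unlist(groups[test_keys], use.names = FALSE))
  list(train = ids[setdiff(seq_along(ids), test)], test = ids[test])
}

# Greedy max-min design over PC coordinates: start from the point farthest
# from the centroid, then repeatedly add the point maximizing its distance to
# the already-selected set.
farthest_point_sample <- function(x, k) {
  n <- nrow(x)
  if (k >= n) return(seq_len(n))
  centroid <- colMeans(x)
  d0 <- sqrt(rowSums((x - matrix(centroid, n, ncol(x), byrow = TRUE))^2))
  sel <- which.max(d0)
  mind <- sqrt(rowSums((x - matrix(x[sel, ], n, ncol(x), byrow = TRUE))^2))
  while (length(sel) < k) {
    cand <- which.max(replace(mind, sel, -Inf))
    sel <- c(sel, cand)
    d <- sqrt(rowSums((x - matrix(x[cand, ], n, ncol(x), byrow = TRUE))^2))
    mind <- pmin(mind, d)
  }
  sort(sel)
}

#' Convert IC50 (molar) to pIC50
#' @param ic50_molar IC50 in mol/L.
#' @return -log10(IC50).
#' @export
pic50 <- function(ic50_molar) {
  stopifnot(all(ic50_molar > 0))
  -log10(ic50_molar)
}
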