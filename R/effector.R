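#' Collect candidate effector genes around a variant
#'
#' Returns up to `max_genes` genes within `window_bp` of the variant (a 2-Mb
#' window, i.e. +/- 1 Mb), sorted by distance to the gene body (0 if the
#' variant lies inside it), with deterministic tie-break by gene id.
#'
#' @param variant_id,chrom,pos variant identifier and coordinates.
#' @param genes data frame with `gene`, `chrom`, `start`, `end` (and
#'   optionally `strand`).
#' @param max_genes cap on candidates (default 10).
#' @param window_bp half-window (default 1 Mb).
#' @return data frame: `variant_id`, `gene`, `distance_bp`, `rank`.
#' @export
collect_candidates <- function(variant_id, chrom, pos, genes, max_genes = 10L,
                               window_bp = 1e6) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) {
    message(sprintf("no gene within window of %s", variant_id))
    return(data.frame(variant_id = character(), gene = character(),
                      distance_bp = numeric(), rank = integer()))
  }
  inside <- pos >= g$start & pos <= g$end
  dist <- ifelse(inside, 0, pmin(abs(pos - g$start), abs(pos - g$end)))
  keep <- dist <= window_bp
  g <- g[keep, , drop = FALSE]; dist <- dist[keep]
  if (nrow(g) == 0) {
    message(sprintf("no gene within window of %s", variant_id))
    return(data.frame(variant_id = character(), gene = character(),
                      distance_bp = numeric(), rank = integer()))
  }
  ord <- order(dist, g$gene)
  ord <- ord[seq_len(min(max_genes, length(ord)))]
  data.frame(variant_id = variant_id, gene = g$gene[ord],
             distance_bp = dist[ord], rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

#' Build the per-(variant, gene) feature matrix
#'
#' Binary evidence flags are set if the variant itself or any proxy at
#' `r^2 >` `proxy_r2` supports the feature: coding consequence on the gene,
#' per-tissue eQTL evidence, metabolic-database membership, OMIM membership,
#' and established drug target (phase III/IV). Distance and closeness rank
#' are carried as numeric features.
#'
#' @param candidates data frame from [collect_candidates()] (stacked).
#' @param coding data frame `variant_id`, `gene` of coding consequences
#'   (or `NULL`).
#' @param eqtl data frame `variant_id`, `gene`, `tissue` (or `NULL`).
#' @param metabolic_genes,omim_genes,drug_genes character vectors (or `NULL`).
#' @param proxies data frame `variant_id`, `proxy_id`, `r2` (or `NULL`).
#' @param proxy_r2 proxy threshold (default 0.6).
#' @return data frame: candidates plus `coding`, one `eqtl_<tissue>` column
#'   per tissue, `metabolic`, `omim`, `drug_target` (all 0/1).
#' @export
build_features <- function(candidates, coding = NULL, eqtl = NULL,
                           metabolic_genes = NULL, omim_genes = NULL,
                           drug_genes = NULL, proxies = NULL, proxy_r2 = 0.6) {
  out <- candidates
  expand <- function(vids) {
    if (is.null(proxies)) return(lapply(vids, identity))
    lapply(vids, function(v) {
      pr <- proxies$proxy_id[proxies$variant_id == v & proxies$r2 > proxy_r2]
      unique(c(v, pr))
    })
  }
  qset <- expand(out$variant_id)

  flag_pair <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0) return(rep(0L, nrow(out)))
    key <- paste(tab$variant_id, tab$gene)
    vapply(seq_len(nrow(out)), function(i) {
      as.integer(any(paste(qset[[i]], out$gene[i]) %in% key))
    }, integer(1))
  }
  if (is.null(coding)) warning("coding table missing: coding features set to 0")
  out$coding <- flag_pair(coding)
  if (is.null(eqtl)) {
    warning("eQTL table missing: eQTL features set to 0")
    out$eqtl_any <- 0L
  } else {
    for (ti in sort(unique(eqtl$tissue))) {
      out[[paste0("eqtl_", ti)]] <- flag_pair(eqtl[eqtl$tissue == ti, ])
    }
    out$eqtl_any <- as.integer(rowSums(out[, grep("^eqtl_", names(out)),
                                           drop = FALSE]) > 0)
  }
  out$metabolic <- as.integer(out$gene %in% (metabolic_genes %||% character(0)))
  out$omim <- as.integer(out$gene %in% (omim_genes %||% character(0)))
  out$drug_target <- as.integer(out$gene %in% (drug_genes %||% character(0)))
  out
}

#' Construct the three putative-true-positive (PTP) training sets
#'
#' Positives are (variant, gene) candidate pairs whose gene belongs to the
#' metabolite class's pathway set and whose variant is fine-mapped for a
#' trait of that class; negatives are the remaining candidates of the same
#' variants. Variants eligible for multiple classes are assigned to exactly
#' one by the fixed priority cholesterol > lipid > amino_acid. Each set is
#' split 7:3 into training and test by variant, so no variant appears in
#' both.
#'
#' @param finemapped data frame `variant_id`, `trait_id` of fine-mapped
#'   associations.
#' @param trait_class named character vector mapping trait id to one of
#'   `cholesterol`, `lipid`, `amino_acid` (other traits are ignored).
#' @param gene_sets named list (`cholesterol`, `lipid`, `amino_acid`) of
#'   pathway gene vectors, e.g. from [read_gmt()].
#' @param candidates stacked candidate table ([collect_candidates()]).
#' @param train_fraction training share of variants (default 0.7).
#' @param seed split seed.
#' @return named list of three PTP sets, each a data frame `variant_id`,
#'   `gene`, `label` (0/1), `split` (`train`/`test`).
#' @export
construct_ptp <- function(finemapped, trait_class, gene_sets, candidates,
                          train_fraction = 0.7, seed = 1L) {
  priority <- c("cholesterol", "lipid", "amino_acid")
  stopifnot(all(priority %in% names(gene_sets)))
  if (any(vapply(gene_sets[priority], length, integer(1)) == 0))
    stop("empty pathway gene set")
  set.seed(seed)
  cls <- trait_class[finemapped$trait_id]
  fm <- data.frame(variant_id = finemapped$variant_id, class = unname(cls),
                   stringsAsFactors = FALSE)
  fm <- fm[!is.na(fm$class), , drop = FALSE]
  # a variant eligible for several classes goes to the highest-priority one
  assigned <- tapply(fm$class, fm$variant_id, function(cc)
    priority[min(match(cc, priority))])
  out <- list()
  for (cl in priority) {
    vids <- names(assigned)[assigned == cl]
    cand <- candidates[candidates$variant_id %in% vids, , drop = FALSE]
    if (nrow(cand) == 0) {
      out[[cl]] <- data.frame(variant_id = character(), gene = character(),
                              label = integer(), split = character())
      next
    }
    label <- as.integer(cand$gene %in% gene_sets[[cl]])
    uv <- unique(cand$variant_id)
    tr <- sample(uv, round(train_fraction * length(uv)))
    out[[cl]] <- data.frame(variant_id = cand$variant_id, gene = cand$gene,
                            label = label,
                            split = ifelse(cand$variant_id %in% tr, "train", "test"),
                            stringsAsFactors = FALSE)
  }
  out
}

# balanced-accuracy of predicted classes vs truth
.balanced_accuracy <- function(truth, pred) {
  sens <- mean(pred[truth == 1] == 1)
  spec <- mean(pred[truth == 0] == 0)
  (sens + spec) / 2
}

#' Train one PTP classifier
#'
#' Random forest tuned by fivefold cross-validation with folds grouped by
#' variant (no variant straddles folds) and with majority-class subsampling
#' in each training fold to counter label imbalance. The `mtry` with the best
#' mean CV balanced accuracy is refit on the full (subsampled) training split
#' and evaluated on the held-out test split (ROC-AUC, balanced accuracy).
#' Columns used to define the PTP labels must already be absent from
#' `features`.
#'
#' @param ptp one PTP set from [construct_ptp()].
#' @param features feature table ([build_features()]) covering the PTP rows.
#' @param feature_cols columns used as predictors (default: all numeric
#'   feature columns except identifiers).
#' @param mtry_grid candidate `mtry` values.
#' @param ntree forest size.
#' @param seed seed for folds, subsampling and forests.
#' @return list with `model`, `mtry`, `cv_balanced_accuracy`,
#'   `test_auc`, `test_balanced_accuracy`, `feature_cols`.
#' @export
train_classifier <- function(ptp, features, feature_cols = NULL,
                             mtry_grid = NULL, ntree = 300L, seed = 1L) {
  set.seed(seed)
  key <- paste(ptp$variant_id, ptp$gene)
  fkey <- paste(features$variant_id, features$gene)
  X <- features[match(key, fkey), , drop = FALSE]
  if (is.null(feature_cols))
    feature_cols <- setdiff(names(X)[vapply(X, is.numeric, logical(1))],
                            c("label"))
  X <- X[, feature_cols, drop = FALSE]
  y <- factor(ptp$label, levels = c(0, 1))
  if (length(unique(y[ptp$split == "train"])) < 2)
    stop("a class is absent from the training split")
  if (is.null(mtry_grid))
    mtry_grid <- unique(pmax(1, round(c(sqrt(ncol(X)), ncol(X) / 3, ncol(X) / 2))))

  tr_idx <- which(ptp$split == "train")
  uv <- unique(ptp$variant_id[tr_idx])
  fold_of_v <- stats::setNames(sample(rep_len(1:5, length(uv))), uv)
  fold <- fold_of_v[ptp$variant_id[tr_idx]]

  subsample <- function(idx) {
    pos <- idx[y[idx] == 1]; neg <- idx[y[idx] == 0]
    nmin <- min(length(pos), length(neg))
    c(sample(pos, nmin), sample(neg, nmin))
  }

  cv_ba <- vapply(mtry_grid, function(mt) {
    mean(vapply(1:5, function(f) {
      tr <- tr_idx[fold != f]; te <- tr_idx[fold == f]
      if (length(unique(y[tr])) < 2 || length(te) == 0) return(NA_real_)
      tr <- subsample(tr)
      rf <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                       mtry = min(mt, ncol(X)), ntree = ntree)
      pred <- stats::predict(rf, X[te, , drop = FALSE])
      .balanced_accuracy(as.integer(as.character(y[te])),
                         as.integer(as.character(pred)))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  best <- mtry_grid[which.max(cv_ba)]

  tr <- subsample(tr_idx)
  model <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                      mtry = min(best, ncol(X)), ntree = ntree)
  te <- which(ptp$split == "test")
  test_auc <- test_ba <- NA_real_
  if (length(te) > 0 && length(unique(y[te])) == 2) {
    prob <- stats::predict(model, X[te, , drop = FALSE], type = "prob")[, "1"]
    test_auc <- as.numeric(pROC::auc(pROC::roc(response = y[te],
                                               predictor = prob,
                                               levels = c("0", "1"),
                                               direction = "<", quiet = TRUE)))
    test_ba <- .balanced_accuracy(as.integer(as.character(y[te])),
                                  as.integer(prob > 0.5))
  }
  list(model = model, mtry = best, cv_balanced_accuracy = max(cv_ba),
       test_auc = test_auc, test_balanced_accuracy = test_ba,
       feature_cols = feature_cols)
}

#' Score candidate genes with the three PTP classifiers
#'
#' The effector-gene score of a candidate is the sum over the three
#' classifiers of its positive-class probability (range 0--3); the median
#' across classifiers is kept as a diagnostic. Per variant, candidates are
#' sorted by score and the assigned gene set is the top block above the
#' largest gap between consecutive scores; if all gaps are equal (including
#' all-zero), no assignment is made and the variant is flagged
#' low-confidence. Confidence tiers: `high` for score >= 2, `moderate` for
#' >= 1.5, else `none`.
#'
#' @param classifiers list of three fitted scorers ([train_classifier()]).
#' @param features candidate feature table.
#' @return `features` augmented with `score`, `score_median`, `tier`,
#'   `assigned`, `low_confidence`.
#' @export
score_genes <- function(classifiers, features) {
  probs <- vapply(classifiers, function(cl) {
    X <- features[, cl$feature_cols, drop = FALSE]
    stats::predict(cl$model, X, type = "prob")[, "1"]
  }, numeric(nrow(features)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  out <- features
  out$score <- rowSums(probs)
  out$score_median <- apply(probs, 1, stats::median)
  out$tier <- ifelse(out$score >= 2, "high",
                     ifelse(out$score >= 1.5, "moderate", "none"))
  out$assigned <- FALSE
  out$low_confidence <- FALSE
  for (v in unique(out$variant_id)) {
    rows <- which(out$variant_id == v)
    if (length(rows) == 1) { out$assigned[rows] <- TRUE; next }
    ord <- rows[order(-out$score[rows], out$gene[rows])]
    gaps <- -diff(out$score[ord])
    if (max(gaps) - min(gaps) < 1e-12) {  # all gaps equal: no assignment
      out$low_confidence[ord] <- TRUE
      next
    }
    cut <- which.max(gaps)
    out$assigned[ord[seq_len(cut)]] <- TRUE
  }
  out
}

#' Fisher's exact enrichment of a query gene set in an annotation set
#'
#' Two-sided Fisher's exact test on the 2x2 table of query membership versus
#' annotation membership over a background of `background_size` genes. The
#' odds ratio is the sample cross-product ratio, with a Haldane 0.5
#' correction if any cell is zero.
#'
#' @param query query gene set (character vector).
#' @param annotation annotation gene set.
#' @param background_size total background gene count (query and annotation
#'   must fit inside it).
#' @return list with `or`, `p`, `table`.
#' @export
fisher_enrichment <- function(query, annotation, background_size) {
  query <- unique(query); annotation <- unique(annotation)
  if (length(query) == 0) stop("empty query set")
  if (length(query) > background_size || length(annotation) > background_size)
    stop("query/annotation larger than background")
  a <- length(intersect(query, annotation))
  b <- length(setdiff(query, annotation))
  cc <- length(setdiff(annotation, query))
  d <- background_size - a - b - cc
  if (d < 0) stop("background smaller than the union of query and annotation")
  tab <- matrix(c(a, b, cc, d), 2, 2,
                dimnames = list(query = c("in", "out"),
                                annotation = c("in", "out")))
  or <- if (any(tab == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  else (a * d) / (b * cc)
  p <- stats::fisher.test(tab)$p.value
  list(or = or, p = p, table = tab)
}

#' Intersection of two effector-gene assignment tables
#'
#' Plumbing for comparing assignments from two pipelines (e.g. against an
#' external colocalization-based assignment): per variant, whether the
#' assigned gene sets agree, overlap or disagree.
#'
#' @param a,b data frames with `variant_id`, `gene` (assigned rows only).
#' @return data frame per shared variant: `variant_id`, `genes_a`, `genes_b`,
#'   `agreement` in `identical`/`overlap`/`disjoint`.
#' @export
compare_assignments <- function(a, b) {
  shared <- intersect(unique(a$variant_id), unique(b$variant_id))
  rows <- lapply(shared, function(v) {
    ga <- sort(unique(a$gene[a$variant_id == v]))
    gb <- sort(unique(b$gene[b$variant_id == v]))
    agree <- if (identical(ga, gb)) "identical"
    else if (length(intersect(ga, gb))) "overlap" else "disjoint"
    data.frame(variant_id = v, genes_a = paste(ga, collapse = ","),
               genes_b = paste(gb, collapse = ","), agreement = agree,
               stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(), genes_a = character(),
               genes_b = character(), agreement = character())
}
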