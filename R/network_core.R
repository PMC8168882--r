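# Data model and I/O for quantitative host-parasitoid networks.
#
# Species identifiers carry a mandatory guild prefix ("H:" for hosts, "P:"
# for parasitoids) so that the two namespaces can never collide in shared
# files. All count matrices are hosts (rows) x parasitoids (columns).

.interaction_cols <- c("site_id", "habitat", "transect", "occasion",
                       "time_step", "host_id", "parasitoid_id", "count")
.habitats   <- c("native", "plantation")
.transects  <- c("edge", "interior")
.time_steps <- c("t", "t_plus_1", "training")
.n_months   <- 7L

is_host_id       <- function(x) startsWith(x, "H:")
is_parasitoid_id <- function(x) startsWith(x, "P:")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a host-parasitoid interaction edge list
#'
#' One row per (site, transect, occasion, host, parasitoid) with the number
#' of rearing ("attack") events observed. Host ids must carry the "H:"
#' prefix and parasitoid ids the "P:" prefix.
#'
#' @param path CSV file with columns `site_id`, `habitat`, `transect`,
#'   `occasion`, `time_step`, `host_id`, `parasitoid_id`, `count`.
#' @return A validated data.frame of interaction records.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop("interaction file not found: ", path)
  validate_interactions(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Validate a table of interaction records
#'
#' Checks the schema and row-level invariants (non-negative integer counts,
#' known habitat/transect/time-step levels, guild prefixes, occasion >= 1).
#' Error messages cite the offending file row (header = row 1).
#'
#' @param records data.frame in the `read_interactions` schema.
#' @return The validated records, columns in canonical order.
#' @export
validate_interactions <- function(records) {
  miss <- setdiff(.interaction_cols, names(records))
  if (length(miss) > 0)
    stop("interaction table is missing column(s): ", paste(miss, collapse = ", "))
  records <- records[.interaction_cols]
  if (nrow(records) == 0L) return(records)
  fail <- function(i, msg)  # +1 converts data-row index to file row
    stop(sprintf("invalid interaction record in row %d: %s", i + 1L, msg))
  cnt <- suppressWarnings(as.numeric(records$count))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))
  if (length(bad) > 0)
    fail(bad[1], sprintf("count '%s' is not a non-negative integer",
                         records$count[bad[1]]))
  records$count <- as.integer(cnt)
  occ <- suppressWarnings(as.numeric(records$occasion))
  bad <- which(is.na(occ) | occ < 1 | occ != floor(occ))
  if (length(bad) > 0) fail(bad[1], "occasion must be an integer >= 1")
  records$occasion <- as.integer(occ)
  bad <- which(!(records$habitat %in% .habitats))
  if (length(bad) > 0)
    fail(bad[1], sprintf("habitat '%s' is not one of %s", records$habitat[bad[1]],
                         paste(.habitats, collapse = "/")))
  bad <- which(!(records$transect %in% .transects))
  if (length(bad) > 0)
    fail(bad[1], sprintf("transect '%s' is not one of %s", records$transect[bad[1]],
                         paste(.transects, collapse = "/")))
  bad <- which(!(records$time_step %in% .time_steps))
  if (length(bad) > 0)
    fail(bad[1], sprintf("time_step '%s' is not one of %s", records$time_step[bad[1]],
                         paste(.time_steps, collapse = "/")))
  bad <- which(!is_host_id(records$host_id))
  if (length(bad) > 0) fail(bad[1], "host_id lacks the 'H:' guild prefix")
  bad <- which(!is_parasitoid_id(records$parasitoid_id))
  if (length(bad) > 0) fail(bad[1], "parasitoid_id lacks the 'P:' guild prefix")
  records
}

#' Write interaction records to CSV
#' @param records validated interaction records.
#' @param path output file.
#' @export
write_interactions <- function(records, path) {
  utils::write.csv(validate_interactions(records), path, row.names = FALSE)
  invisible(path)
}

#' Construct a meta-network object directly from a count matrix
#'
#' @param matrix hosts x parasitoids matrix of pooled attack counts (or 0/1
#'   occurrences in binary mode). Row and column names are species ids.
#' @param mode "weighted" or "binary".
#' @param provenance which habitat pool the matrix came from.
#' @param sites site ids pooled into the matrix.
#' @export
meta_network <- function(matrix, mode = c("weighted", "binary"),
                         provenance = "combined", sites = character()) {
  mode <- match.arg(mode)
  if (!is.matrix(matrix) || is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("meta-network needs a matrix with host row names and parasitoid column names")
  if (any(matrix < 0) || any(!is.finite(matrix)))
    stop("meta-network entries must be finite and non-negative")
  if (mode == "binary" && !all(matrix %in% c(0, 1)))
    stop("binary meta-network entries must be 0 or 1")
  structure(list(matrix = matrix, mode = mode, provenance = provenance,
                 sites = sites),
            class = "meta_network")
}

#' Pool interaction records into a quantitative training meta-network
#'
#' Sums attack counts over all records that match the habitat filter
#' (pooling across sites, transects and occasions). In binary mode an entry
#' is 1 iff the pooled count is positive. Pooling is order-independent.
#'
#' @param records interaction records (typically the training time step).
#' @param habitat_filter "native", "plantation" or "combined".
#' @param mode "weighted" (counts) or "binary" (occurrence).
#' @return A `meta_network`.
#' @export
pool_meta_network <- function(records,
                              habitat_filter = c("combined", "native", "plantation"),
                              mode = c("weighted", "binary")) {
  habitat_filter <- match.arg(habitat_filter)
  mode <- match.arg(mode)
  records <- validate_interactions(records)
  if (habitat_filter != "combined")
    records <- records[records$habitat == habitat_filter, , drop = FALSE]
  if (nrow(records) == 0L)
    stop("no interaction records match habitat filter '", habitat_filter, "'")
  hosts <- sort(unique(records$host_id))
  paras <- sort(unique(records$parasitoid_id))
  m <- matrix(0, length(hosts), length(paras), dimnames = list(hosts, paras))
  agg <- stats::aggregate(count ~ host_id + parasitoid_id, data = records, FUN = sum)
  m[cbind(match(agg$host_id, hosts), match(agg$parasitoid_id, paras))] <- agg$count
  if (mode == "binary") m[] <- as.numeric(m > 0)
  meta_network(m, mode, habitat_filter, sites = sort(unique(records$site_id)))
}

#' Binarize a weighted meta-network
#' @param meta a `meta_network`.
#' @export
binarize_meta <- function(meta) {
  stopifnot(inherits(meta, "meta_network"))
  m <- meta$matrix
  m[] <- as.numeric(m > 0)
  meta_network(m, "binary", meta$provenance, meta$sites)
}

#' @export
print.meta_network <- function(x, ...) {
  cat(sprintf("meta_network (%s, %s): %d hosts x %d parasitoids, %d links, %d sites pooled\n",
              x$mode, x$provenance, nrow(x$matrix), ncol(x$matrix),
              sum(x$matrix > 0), length(x$sites)))
  invisible(x)
}

#' Normalised degree of a species in a meta-network
#'
#' Number of distinct partners with a positive entry divided by the number
#' of possible partners in the network; a generality measure in [0, 1].
#'
#' @param network a `meta_network`.
#' @param species_id species identifier (with guild prefix).
#' @param guild "host" or "parasitoid".
#' @export
normalised_degree <- function(network, species_id, guild = c("host", "parasitoid")) {
  guild <- match.arg(guild)
  stopifnot(inherits(network, "meta_network"))
  m <- network$matrix
  if (guild == "host") {
    if (!species_id %in% rownames(m)) stop("unknown host in network: ", species_id)
    sum(m[species_id, ] > 0) / ncol(m)
  } else {
    if (!species_id %in% colnames(m)) stop("unknown parasitoid in network: ", species_id)
    sum(m[, species_id] > 0) / nrow(m)
  }
}

#' Schoener overlap between two monthly phenology vectors
#'
#' Vectors are normalised to proportions internally; the overlap is
#' sum_m min(p_m, q_m), in [0, 1], symmetric, and invariant to rescaling
#' either input by a positive constant.
#'
#' @param p,q non-negative per-month abundance vectors of equal length.
#' @export
phenological_overlap <- function(p, q) {
  if (length(p) != length(q)) stop("phenology vectors differ in length")
  if (any(p < 0) || any(q < 0)) stop("phenology entries must be non-negative")
  sp <- sum(p); sq <- sum(q)
  if (sp <= 0 || sq <= 0) stop("phenology unknown: all-zero monthly vector")
  sum(pmin(p / sp, q / sq))
}

#' Parasitism rate: events per host individual sampled
#' @param events number of parasitism events (>= 0).
#' @param sampled number of host individuals collected (> 0).
#' @export
parasitism_rate <- function(events, sampled) {
  if (any(events < 0)) stop("events must be non-negative")
  if (any(sampled <= 0)) stop("host not collected: sampled must be positive")
  events / sampled
}

#' Principal-coordinate representation of a phylogeny
#'
#' Decomposes the patristic (cophenetic) distance matrix by classical
#' multidimensional scaling. Axes are ordered by decreasing eigenvalue and
#' axes with non-positive eigenvalues are dropped, so for
#' Euclidean-embeddable inputs pairwise Euclidean distances over all
#' retained axes reproduce the patristic distances.
#'
#' @param tree a `phylo` object, a Newick string, or a path to a Newick file.
#' @param m number of coordinate axes to retain (1 <= m <= tips - 1).
#' @return An object of class `phylo_coords`: list with `coords` (species x
#'   axes), `variance_fractions`, and `species`.
#' @export
patristic_coordinates <- function(tree, m) {
  phy <- if (inherits(tree, "phylo")) {
    tree
  } else if (is.character(tree) && length(tree) == 1 && file.exists(tree)) {
    ape::read.tree(tree)
  } else if (is.character(tree)) {
    tryCatch(ape::read.tree(text = tree),
             error = function(e) NULL, warning = function(w) NULL)
  } else {
    stop("tree must be a phylo object, Newick text, or a file path")
  }
  if (is.null(phy)) stop("could not parse Newick tree")
  if (anyDuplicated(phy$tip.label) > 0) stop("duplicate tip labels in tree")
  n <- length(phy$tip.label)
  if (m < 1 || m > n - 1) stop("number of axes m must be in [1, tips - 1]")
  d <- ape::cophenetic.phylo(phy)
  pc <- suppressWarnings(stats::cmdscale(d, k = m, eig = TRUE))
  pts <- pc$points
  eig <- pc$eig
  keep <- which(eig[seq_len(ncol(pts))] > 1e-9 * max(abs(eig)))
  if (length(keep) == 0) stop("no positive-eigenvalue axes retained")
  coords <- pts[, keep, drop = FALSE]
  colnames(coords) <- paste0("axis", seq_along(keep))
  structure(list(coords = coords,
                 variance_fractions = eig[keep] / sum(pmax(eig, 0)),
                 species = rownames(coords)),
            class = "phylo_coords")
}

#' Summed abundance of a species across sites and sampling dates
#'
#' Hosts: total individuals collected (from the host sample tables).
#' Parasitoids: total rearing events (attack counts in the records).
#'
#' @param species_id species id with guild prefix.
#' @param records interaction records (needed for parasitoids).
#' @param host_samples host sample table with columns `host_id`, `n`
#'   (needed for hosts).
#' @export
total_abundance <- function(species_id, records = NULL, host_samples = NULL) {
  if (is_host_id(species_id)) {
    if (is.null(host_samples) || !species_id %in% host_samples$host_id)
      stop("species absent from host sample tables: ", species_id)
    sum(host_samples$n[host_samples$host_id == species_id])
  } else if (is_parasitoid_id(species_id)) {
    if (is.null(records) || !species_id %in% records$parasitoid_id)
      stop("species absent from interaction records: ", species_id)
    sum(records$count[records$parasitoid_id == species_id])
  } else {
    stop("species id lacks a guild prefix ('H:' or 'P:'): ", species_id)
  }
}

# ---- trait tables ----------------------------------------------------------

.trait_cols <- c("species_id", "guild", "body_size", "biogeographic_status",
                 paste0("pheno_m", seq_len(7L)), "nd", "total_abundance")

#' Read a per-species trait table
#'
#' Columns: species_id, guild, body_size, biogeographic_status (hosts only;
#' NA for parasitoids), pheno_m1..pheno_m7 (monthly abundances), nd
#' (normalised degree; may be NA until computed), total_abundance.
#'
#' @param path CSV file.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("trait file not found: ", path)
  validate_traits(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Validate a trait table
#' @param traits data.frame in the `read_traits` schema.
#' @export
validate_traits <- function(traits) {
  miss <- setdiff(.trait_cols, names(traits))
  if (length(miss) > 0)
    stop("trait table is missing column(s): ", paste(miss, collapse = ", "))
  traits <- traits[.trait_cols]
  if (anyDuplicated(traits$species_id) > 0)
    stop("duplicate species_id in trait table")
  if (!all(traits$guild %in% c("host", "parasitoid")))
    stop("guild must be 'host' or 'parasitoid'")
  if (any(!is.na(traits$body_size) & traits$body_size <= 0))
    stop("body_size must be positive")
  nd <- traits$nd
  if (any(!is.na(nd) & (nd < 0 | nd > 1)))
    stop("nd must lie in [0, 1]")
  ph <- as.matrix(traits[paste0("pheno_m", seq_len(.n_months))])
  if (any(!is.na(ph) & ph < 0)) stop("phenology entries must be non-negative")
  st <- traits$biogeographic_status
  host <- traits$guild == "host"
  if (any(host & (is.na(st) | !(st %in% c("native", "exotic")))))
    stop("hosts must have biogeographic_status 'native' or 'exotic'")
  traits
}

#' Write a trait table to CSV
#' @param traits validated trait table.
#' @param path output file.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(validate_traits(traits), path, row.names = FALSE)
  invisible(path)
}

#' Monthly phenology matrix from a trait table
#' @param traits validated trait table.
#' @return species x months matrix, rownames = species ids.
#' @export
pheno_matrix <- function(traits) {
  ph <- as.matrix(traits[paste0("pheno_m", seq_len(.n_months))])
  rownames(ph) <- traits$species_id
  ph
}

# ---- site networks ---------------------------------------------------------

#' Build a single site x time-step quantitative network
#'
#' Rows cover every host either reared or collected at the site/time step;
#' columns cover every parasitoid reared there. `host_sample` maps each host
#' to the number of individuals collected. A host with a positive attack row
#' must have been collected (validated).
#'
#' @param records interaction records.
#' @param host_samples host sample table (`site_id`, `time_step`, `host_id`, `n`).
#' @param site site id.
#' @param time_step one of "t", "t_plus_1", "training".
#' @return An object of class `site_network`.
#' @export
build_site_network <- function(records, host_samples, site, time_step) {
  r <- records[records$site_id == site & records$time_step == time_step, , drop = FALSE]
  hs <- host_samples[host_samples$site_id == site &
                     host_samples$time_step == time_step, , drop = FALSE]
  samp <- if (nrow(hs) > 0) tapply(hs$n, hs$host_id, sum) else numeric(0)
  hosts <- sort(unique(c(r$host_id, names(samp))))
  paras <- sort(unique(r$parasitoid_id))
  m <- matrix(0, length(hosts), length(paras), dimnames = list(hosts, paras))
  if (nrow(r) > 0) {
    agg <- stats::aggregate(count ~ host_id + parasitoid_id, data = r, FUN = sum)
    m[cbind(match(agg$host_id, hosts), match(agg$parasitoid_id, paras))] <- agg$count
  }
  full_samp <- stats::setNames(rep(0, length(hosts)), hosts)
  full_samp[names(samp)] <- samp
  attacked <- rownames(m)[rowSums(m) > 0]
  bad <- attacked[full_samp[attacked] <= 0]
  if (length(bad) > 0)
    stop("host(s) with attacks but no collected individuals at ", site, "/",
         time_step, ": ", paste(bad, collapse = ", "))
  structure(list(site_id = site, time_step = time_step,
                 count_matrix = m, host_sample = full_samp),
            class = "site_network")
}
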