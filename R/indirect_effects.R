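# Projection of quantitative networks into indirect effects: the potential
# for apparent competition d_ij among hosts, attack rates from predicted or
# observed networks, and expected parasitism rates under host abundance
# change.

#' Potential for apparent competition d_ij
#'
#' For hosts i, j and parasitoids k with link strengths (attack counts)
#' alpha:
#'   d_ij = sum_k (alpha_ik / sum_l alpha_il) * (alpha_jk / sum_m alpha_mk)
#' the proportion of the parasitoids attacking host i expected to have
#' recruited from host j. Rows of parasitized hosts sum to one; hosts with
#' no parasitoids get an all-zero row flagged invalid.
#'
#' @param meta weighted `meta_network` (hosts x parasitoids counts).
#' @return object of class `apparent_competition`: list with `d` (H x H),
#'   `valid` (named logical) and `hosts`.
#' @export
potential_apparent_competition <- function(meta) {
  stopifnot(inherits(meta, "meta_network"))
  if (meta$mode != "weighted") stop("d_ij needs a weighted meta-network")
  A <- meta$matrix
  if (length(A) == 0) stop("empty meta-network")
  row_tot <- rowSums(A)
  col_tot <- colSums(A)
  share   <- A / ifelse(row_tot > 0, row_tot, 1)          # alpha_ik / sum_l alpha_il
  recruit <- sweep(A, 2, ifelse(col_tot > 0, col_tot, 1), "/")  # alpha_jk / sum_m alpha_mk
  d <- share %*% t(recruit)
  dimnames(d) <- list(rownames(A), rownames(A))
  structure(list(d = d,
                 valid = stats::setNames(row_tot > 0, rownames(A)),
                 hosts = rownames(A)),
            class = "apparent_competition")
}

#' Attack-rate matrix from a predicted (or observed) network
#'
#' Sources: "rf" converts occurrence probabilities into expected attack
#' counts (p-hat times the host's time-t abundance, the default convention;
#' `rf_convention = "p_raw"` passes probabilities through unchanged); "knn"
#' passes predicted frequencies through; "observed" copies the observed
#' time-t site network.
#'
#' @param pred probability or frequency matrix (hosts x parasitoids) with a
#'   `site_id` attribute; ignored for source "observed".
#' @param source "rf", "knn" or "observed".
#' @param abundances data.frame with `host_id`, `n_t` (required for "rf").
#' @param site_network observed `site_network` at time t (for "observed").
#' @param rf_convention "p_times_n" or "p_raw".
#' @return object of class `attack_rates`.
#' @export
attack_rates_from_predictions <- function(pred = NULL,
                                          source = c("rf", "knn", "observed"),
                                          abundances = NULL,
                                          site_network = NULL,
                                          rf_convention = c("p_times_n", "p_raw")) {
  source <- match.arg(source)
  rf_convention <- match.arg(rf_convention)
  if (source == "observed") {
    stopifnot(inherits(site_network, "site_network"))
    alpha <- site_network$count_matrix
    site_id <- site_network$site_id
  } else if (source == "knn") {
    stopifnot(is.matrix(pred))
    if (any(pred < 0)) stop("predicted frequencies must be non-negative")
    alpha <- pred
    site_id <- attr(pred, "site_id") %||% NA_character_
  } else {
    stopifnot(is.matrix(pred))
    site_id <- attr(pred, "site_id") %||% NA_character_
    if (rf_convention == "p_raw") {
      alpha <- pred
    } else {
      if (is.null(abundances)) stop("rf attack rates need time-t host abundances")
      n <- stats::setNames(abundances$n_t, abundances$host_id)
      hosts <- rownames(pred)
      nv <- n[hosts]
      bad <- hosts[rowSums(pred) > 0 & (is.na(nv) | !is.finite(nv))]
      if (length(bad) > 0)
        stop("host(s) with positive predicted probability but no time-t abundance: ",
             paste(bad, collapse = ", "))
      nv[is.na(nv)] <- 0
      alpha <- pred * as.numeric(nv)  # recycles down rows: alpha_il = p_il * n_i
    }
  }
  if (any(!is.finite(alpha)) || any(alpha < 0))
    stop("attack rates must be finite and non-negative")
  structure(list(matrix = alpha, site_id = site_id, source = source),
            class = "attack_rates")
}

#' Expected parasitism rate at time t+1 per host
#'
#' E_i(t+1) = (1 / n_i(t+1)) * sum_j d_ij * (sum_l alpha_ilt) * (n_j(t+1) / n_jt)
#'
#' where the sum over donors j runs over the site's hosts with positive
#' time-t abundance (donors with n_jt = 0 are skipped with a warning). A
#' host is eligible iff it was collected at both time steps and has a
#' non-zero summed attack rate at time t; additionally a focal host absent
#' from the d_ij host set (or with an all-zero flagged row) has no
#' apparent-competition estimate and is marked ineligible.
#'
#' @param d `apparent_competition` matrix.
#' @param attacks `attack_rates` at time t for the site.
#' @param abundances data.frame with `host_id`, `n_t`, `n_t_plus_1` for the
#'   site's hosts.
#' @return data.frame with site_id, host_id, E (NA when ineligible),
#'   eligible, exclusion_reason.
#' @export
expected_parasitism <- function(d, attacks, abundances) {
  stopifnot(inherits(d, "apparent_competition"),
            inherits(attacks, "attack_rates"))
  req <- c("host_id", "n_t", "n_t_plus_1")
  miss <- setdiff(req, names(abundances))
  if (length(miss) > 0)
    stop("abundance table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(abundances$n_t < 0) || any(abundances$n_t_plus_1 < 0))
    stop("abundances must be non-negative")
  hosts <- abundances$host_id
  if (anyDuplicated(hosts) > 0) stop("duplicate hosts in abundance table")
  alpha <- attacks$matrix
  a_sum <- stats::setNames(rep(0, length(hosts)), hosts)
  in_alpha <- intersect(hosts, rownames(alpha))
  a_sum[in_alpha] <- rowSums(alpha)[in_alpha]
  n0 <- stats::setNames(abundances$n_t, hosts)
  n1 <- stats::setNames(abundances$n_t_plus_1, hosts)

  donors_all <- intersect(hosts, d$hosts)
  skipped <- donors_all[n0[donors_all] == 0]
  if (length(skipped) > 0)
    warning("donor host(s) with zero time-t abundance skipped: ",
            paste(skipped, collapse = ", "))
  donors <- donors_all[n0[donors_all] > 0]
  ratio <- n1[donors] / n0[donors]

  res <- lapply(hosts, function(h) {
    reason <- NA_character_
    if (n0[h] == 0 || n1[h] == 0) {
      reason <- "not collected at both time steps"
    } else if (a_sum[h] <= 0) {
      reason <- "zero predicted attack rate at time t"
    } else if (!(h %in% d$hosts) || !d$valid[h]) {
      reason <- "no apparent-competition estimate"
    }
    if (!is.na(reason)) {
      data.frame(site_id = attacks$site_id, host_id = h, E = NA_real_,
                 eligible = FALSE, exclusion_reason = reason,
                 stringsAsFactors = FALSE)
    } else {
      e <- (a_sum[h] / n1[h]) * sum(d$d[h, donors] * ratio)
      data.frame(site_id = attacks$site_id, host_id = h, E = as.numeric(e),
                 eligible = TRUE, exclusion_reason = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Observed parasitism rates at a site/time step
#'
#' Per collected host: events = total attacks capped at the number of
#' individuals sampled (each collected individual counts at most once under
#' rearing semantics); rate = events / sampled. Hosts not collected produce
#' no record.
#'
#' @param site_network a `site_network`, typically at time t+1.
#' @return data.frame with site_id, host_id, events, sampled, rate.
#' @export
observed_parasitism <- function(site_network) {
  stopifnot(inherits(site_network, "site_network"))
  samp <- site_network$host_sample
  hosts <- names(samp)[samp > 0]
  if (length(hosts) == 0)
    return(data.frame(site_id = character(0), host_id = character(0),
                      events = numeric(0), sampled = numeric(0),
                      rate = numeric(0), stringsAsFactors = FALSE))
  ev <- stats::setNames(rep(0, length(hosts)), hosts)
  in_m <- intersect(hosts, rownames(site_network$count_matrix))
  ev[in_m] <- rowSums(site_network$count_matrix)[in_m]
  events <- pmin(ev, samp[hosts])
  data.frame(site_id = site_network$site_id, host_id = hosts,
             events = as.numeric(events), sampled = as.numeric(samp[hosts]),
             rate = as.numeric(events / samp[hosts]),
             stringsAsFactors = FALSE, row.names = NULL)
}
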