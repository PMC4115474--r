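# Shared fixtures, built in code.

fixture_catalog <- function() {
  read_task_catalog(system.file("extdata", "tasks_synthetic.json",
                                package = "rehabplan"))
}

fixture_norms <- function() {
  read_normative_map(system.file("extdata", "norms_synthetic.json",
                                 package = "rehabplan"))
}

# the worked-example impairment profile: attention 3/2/3, memory 2/1/3,
# executive 1/0/1/2/0
table2_profile <- function() {
  cognitive_profile(c(3, 2, 3, 2, 1, 3, 1, 0, 1, 2, 0))
}

bingo_task <- function() {
  cat <- fixture_catalog()
  cat[[which(task_ids(cat) == "bingo")]]
}

# minimal task definition; single binary parameter unless given
make_task <- function(task_id, subfunction = "sustained",
                      cc = NULL, duration = 5,
                      parameters = list(list(name = "p1",
                                             values = c("a", "b"),
                                             weights = c(0L, 1L)))) {
  if (is.null(cc)) {
    cc <- stats::setNames(rep(0L, 11L), subfunction_names())
    cc[subfunction] <- 4L
  }
  list(task_id = task_id, name = task_id, subfunction = subfunction,
       cc = cc, parameters = parameters, duration = duration)
}

# catalog of n tasks with strictly distinct clinical scores for the
# all-ones profile (cc on the designated subfunction varies row by row)
distinct_gss_catalog <- function(n = 12, duration = 5) {
  sfn <- subfunction_names()
  lapply(seq_len(n), function(i) {
    des <- sfn[(i - 1L) %% 11L + 1L]
    cc <- stats::setNames(rep(0L, 11L), sfn)
    cc[des] <- 1L
    t <- make_task(sprintf("d%02d", i), subfunction = des, cc = cc,
                   duration = duration)
    t$cc[des] <- 1L
    t
  })
}

# profile whose clinical scores against distinct_gss_catalog are distinct:
# impairment i on the subfunction designated by task i is impossible on a
# 0-4 scale for 12 tasks, so instead vary cc weights here
distinct_gss_scores <- function(catalog) {
  # hand the scorer a breakdown with strictly decreasing GSS by task order
  data.frame(task_id = task_ids(catalog),
             U = 0L, I = 0,
             ILCC = rev(seq_along(catalog)),
             GSS = rev(seq_along(catalog)))
}

make_outcome <- function(pre, post, tasks) {
  list(pre = pre, post = post, tasks = tasks)
}
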