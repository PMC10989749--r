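#' Run a task graph with dynamic dispatch over worker processes
#'
#' Tasks declare dependencies; a task becomes ready when all its
#' dependencies completed. With `threads > 1` on a fork-capable OS, up to
#' `threads` ready tasks run concurrently in forked workers and the next
#' ready task is dispatched to the next free worker (dynamic load
#' balancing); otherwise tasks run sequentially in definition order. A task
#' must be a pure function of its declared inputs (typically reading and
#' writing files), so the produced outputs are identical for any thread
#' count. A failing task is recorded and its transitive dependents are
#' cancelled; independent tasks continue.
#'
#' @param tasks Named list; each element is `list(fun = function(results)
#'   ..., deps = character())`. `fun` receives the named list of its
#'   dependencies' return values.
#' @param threads Maximum number of tasks in flight.
#' @return list(log = data.frame(task, status, order), results = named list,
#'   errors = named character) — `status` is "done", "failed" or
#'   "cancelled"; `order` is the completion order.
#' @export
schedule <- function(tasks, threads = 1L) {
  ids <- names(tasks)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids)) {
    stop("tasks must have unique non-empty names")
  }
  deps <- lapply(tasks, function(t) unique(t$deps %||% character(0)))
  unknown <- setdiff(unlist(deps), ids)
  if (length(unknown)) stop("unknown dependency: ", unknown[1L])

  # Kahn's algorithm: cycle check + a deterministic topological order
  indeg <- vapply(deps, length, 0L)
  dependents <- lapply(ids, function(i) ids[vapply(deps, function(d) i %in% d, TRUE)])
  names(dependents) <- ids
  queue <- ids[indeg == 0L]
  seen <- character(0)
  indeg2 <- indeg
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    seen <- c(seen, cur)
    for (dn in dependents[[cur]]) {
      indeg2[dn] <- indeg2[dn] - 1L
      if (indeg2[dn] == 0L) queue <- c(queue, dn)
    }
  }
  if (length(seen) != length(ids)) {
    stop("cycle in task graph involving: ",
         paste(setdiff(ids, seen), collapse = ", "))
  }

  status <- stats::setNames(rep("pending", length(ids)), ids)
  results <- stats::setNames(vector("list", length(ids)), ids)
  errors <- character(0)
  order_log <- character(0)

  cancel_dependents <- function(id) {
    for (dn in dependents[[id]]) {
      if (status[dn] %in% c("pending", "ready")) {
        status[dn] <<- "cancelled"
        order_log <<- c(order_log, dn)
        cancel_dependents(dn)
      }
    }
  }
  finish <- function(id, res) {
    if (inherits(res, "ampliflow_task_error")) {
      status[id] <<- "failed"
      errors[id] <<- res$message
      order_log <<- c(order_log, id)
      cancel_dependents(id)
    } else {
      status[id] <<- "done"
      results[[id]] <<- res$value
      order_log <<- c(order_log, id)
    }
  }
  # the wrapper never returns NULL, so an unfinished forked job (NULL from
  # mccollect) cannot be confused with a completed one
  run_task <- function(id) {
    tryCatch(list(value = tasks[[id]]$fun(results[deps[[id]]])),
             error = function(e) structure(list(message = conditionMessage(e)),
                                           class = "ampliflow_task_error"))
  }
  ready <- function() {
    ids[vapply(ids, function(i) {
      status[i] == "pending" && all(status[deps[[i]]] == "done")
    }, TRUE)]
  }

  use_fork <- threads > 1L && .Platform$OS.type == "unix"
  if (!use_fork) {
    while (length(r <- ready())) {
      for (id in r) {
        if (status[id] != "pending") next
        if (!all(status[deps[[id]]] == "done")) next
        finish(id, run_task(id))
      }
    }
  } else {
    jobs <- list()  # pid-keyed: task id
    repeat {
      for (id in ready()) {
        if (length(jobs) >= threads) break
        status[id] <- "running"
        job <- parallel::mcparallel(run_task(id))
        jobs[[as.character(job$pid)]] <- list(id = id, job = job)
      }
      if (!length(jobs)) {
        if (!length(ready())) break
        next
      }
      got <- parallel::mccollect(lapply(jobs, function(j) j$job),
                                 wait = FALSE, timeout = 10)
      if (is.null(got) || !length(got)) next
      for (pid in names(got)) {
        if (is.null(got[[pid]]) || !pid %in% names(jobs)) next
        res <- got[[pid]]
        if (inherits(res, "try-error")) {
          res <- structure(list(message = as.character(res)),
                           class = "ampliflow_task_error")
        }
        finish(jobs[[pid]]$id, res)
        jobs[[pid]] <- NULL
      }
    }
  }
  list(log = data.frame(task = order_log,
                        status = unname(status[order_log]),
                        order = seq_along(order_log),
                        stringsAsFactors = FALSE),
       results = results,
       errors = errors)
}
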