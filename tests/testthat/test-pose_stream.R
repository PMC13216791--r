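test_that("detections validate keypoint names, uniqueness and confidences", {
  expect_error(pose_detection(0, 0, kp1("elbow_left", 1, 1)), "unknown keypoint")
  expect_error(pose_detection(0, 0, rbind(kp1("nose", 1, 1), kp1("nose", 2, 2))),
               "duplicate")
  expect_error(pose_detection(0, 0, kp1("nose", 1, 1, conf = 1.5)), "confidence")
  d <- pose_detection(3, 0.1, kp1("nose", 1, 1), provisional_id = 7)
  expect_identical(d$frame_index, 3L)
  expect_identical(d$provisional_id, 7)
})

test_that("stream reading handles fixtures, empty files and bad ordering", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"frame":0,"t":0,"detections":[{"id":1,"conf":0.9,"kp":{"nose":[5,5,0.9]}}]}',
    '{"frame":1,"t":0.033,"detections":[]}',
    '{"frame":2,"t":0.066,"detections":[{"conf":0.8,"kp":{"left_wrist":[7,2,0.8]}}]}'
  ), path)
  s <- read_stream(path)
  expect_identical(n_frames(s), 3L)
  expect_length(s$frames[[1]]$detections, 1L)
  expect_length(s$frames[[2]]$detections, 0L)
  expect_identical(s$frames[[3]]$detections[[1]]$keypoints$name, "left_wrist")

  empty <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), empty)
  expect_identical(n_frames(read_stream(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"frame":0,"detections":[]}', '{"frame":2,"detections":[]}',
               '{"frame":1,"detections":[]}'), bad)
  expect_error(read_stream(bad), "line 3")

  unk <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"frame":0,"detections":[{"conf":1,"kp":{"tail":[1,1,1]}}]}', unk)
  expect_error(read_stream(unk), "unknown keypoint")

  mangled <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"frame":0,"detections":[]}', '{"frame":1, oops'), mangled)
  expect_error(read_stream(mangled), "line 2")
})

test_that("write/read round-trip is an identity at full precision", {
  set.seed(3)
  layout <- room_layout()
  scene <- simulate_scene(layout,
                          list(trajectory_script(1, data.frame(
                            time_s = c(0, 3), x = c(60, 320), y = c(300, 300)))),
                          noise_model(keypoint_jitter_sd = 2,
                                      dropout_prob = 0.1, seed = 5),
                          duration_s = 3)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_stream(scene$stream, path)
  back <- read_stream(path, frame_rate = scene$stream$frame_rate,
                      source_id = scene$stream$source_id)
  expect_identical(n_frames(back), n_frames(scene$stream))
  for (i in seq_len(n_frames(back))) {
    a <- scene$stream$frames[[i]]; b <- back$frames[[i]]
    expect_identical(b$frame, a$frame)
    expect_identical(b$t, a$t)
    expect_identical(length(b$detections), length(a$detections))
    for (j in seq_along(a$detections)) {
      ka <- a$detections[[j]]$keypoints; kb <- b$detections[[j]]$keypoints
      rownames(ka) <- rownames(kb) <- NULL
      expect_identical(kb, ka)
    }
  }

  # awkward float preserved exactly, frames with zero detections kept
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  s <- detection_stream(list(
    list(frame = 0L, t = 0,
         detections = list(pose_detection(0, 0, kp1("nose", 1.1, 2.2,
                                                    0.123456789)))),
    list(frame = 1L, t = 1 / 30, detections = list())), frame_rate = 30)
  write_stream(s, path2)
  b <- read_stream(path2)
  expect_identical(b$frames[[1]]$detections[[1]]$keypoints$confidence,
                   0.123456789)
  expect_length(b$frames[[2]]$detections, 0L)
})

test_that("face redaction boxes cover head landmarks with padding", {
  det <- pose_detection(0, 0, rbind(kp1("nose", 50, 40),
                                    kp1("left_ear", 45, 42),
                                    kp1("right_ear", 55, 42)))
  box <- face_redaction_regions(det, padding = 10)
  expect_equal(as.numeric(box), c(35, 30, 65, 52))
  expect_false(attr(box, "fallback"))

  # degenerate single-point box inflated to the 1-pixel minimum
  single <- pose_detection(0, 0, kp1("nose", 50, 40))
  b1 <- face_redaction_regions(single, padding = 0)
  expect_equal(as.numeric(b1), c(49.5, 39.5, 50.5, 40.5))

  # no head landmark above threshold: upper third of the body box
  # (body spans y 40..160, so the fallback covers y 40..80)
  body <- pose_detection(0, 0, rbind(kp1("nose", 50, 40, 0.2),
                                     kp1("left_hip", 40, 100),
                                     kp1("left_ankle", 42, 160)))
  bf <- face_redaction_regions(body, padding = 10)
  expect_true(attr(bf, "fallback"))
  expect_equal(as.numeric(bf)[c(2, 4)], c(40, 80))
})

test_that("redaction boxes always contain the head landmarks that built them", {
  set.seed(9)
  for (rep in 1:25) {
    nh <- sample(1:5, 1)
    heads <- data.frame(name = sample(c("nose", "left_eye", "right_eye",
                                        "left_ear", "right_ear"), nh),
                        x = stats::runif(nh, 0, 640),
                        y = stats::runif(nh, 0, 480),
                        confidence = stats::runif(nh, 0.5, 1))
    det <- pose_detection(0, 0, heads)
    box <- face_redaction_regions(det, padding = stats::runif(1, 0, 20))
    expect_true(all(heads$x >= box[["x_min"]] & heads$x <= box[["x_max"]] &
                      heads$y >= box[["y_min"]] & heads$y <= box[["y_max"]]))
  }
})

test_that("stream-level redaction table has one row per detection", {
  sc <- simulate_scene(room_layout(),
                       list(trajectory_script(1, data.frame(
                         time_s = 0, x = 320, y = 100))),
                       noise_model(seed = 2), duration_s = 1)
  tab <- redaction_table(sc$stream)
  nd <- sum(vapply(sc$stream$frames, function(f) length(f$detections),
                   integer(1)))
  expect_identical(nrow(tab), nd)
  expect_true(all(tab$x_min < tab$x_max & tab$y_min < tab$y_max))
})
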