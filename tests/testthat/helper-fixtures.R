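# Shared fixtures, built once per test run and cached in this environment.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixtureCache)) assign(key, expr, .fixtureCache)
  get(key, .fixtureCache)
}

# small unpaired two-domain fixture: 4 classes x 3, 16^3
tinyFixture <- function() {
  cached("tiny", generateFixtureDatasets(3, size = 16, seed = 42))
}

# labeled clean fixture for embedder/classifier work: 4 classes x 8, 16^3
embFixture <- function() {
  cached("emb", generateFixtureDatasets(8, size = 16, seed = 99)$D)
}

tinyModel <- function() {
  cached("model", buildModel(16, seed = 7, baseFilters = 4L))
}

structuredVolume <- function(n = 16, seed = 3) {
  makeToyDensity("dumbbell", n = n, seed = seed)
}

# brute-force k-NN manifold metric oracle (naive double loops)
bruteManifold <- function(X, Y, k) {
  N <- nrow(X); M <- nrow(Y)
  euc <- function(a, b) sqrt(sum((a - b)^2))
  radii <- sapply(seq_len(N), function(i) {
    d <- sapply(seq_len(N)[-i], function(j) euc(X[i, ], X[j, ]))
    sort(d)[k]
  })
  inBall <- matrix(FALSE, M, N)
  for (j in seq_len(M)) for (i in seq_len(N)) {
    inBall[j, i] <- euc(X[i, ], Y[j, ]) <= radii[i]
  }
  radiiY <- sapply(seq_len(M), function(i) {
    d <- sapply(seq_len(M)[-i], function(j) euc(Y[i, ], Y[j, ]))
    sort(d)[k]
  })
  xInY <- sapply(seq_len(N), function(i) {
    any(sapply(seq_len(M), function(j) euc(Y[j, ], X[i, ]) <= radiiY[j]))
  })
  list(precision = mean(apply(inBall, 1, any)),
       recall = mean(xInY),
       density = sum(inBall) / (k * M),
       coverage = mean(apply(inBall, 2, any)))
}
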