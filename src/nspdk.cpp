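#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Explicit feature map of the neighborhood-subgraph-pairwise-distance (NSPD)
// kernel on directed annotated (hyper)graphs.
//
// Features (per spec of the kernel):
//  * pair features: for every ordered root pair (u, v) of the same feature set
//    (ground/ground via backbone+base-pair edges, abstract/abstract via
//    abstract-adjacency edges) with directed shortest-path distance d <= D over
//    traversable edges, and every radius r <= R, one feature keyed by
//    (r, d, set, nbh_r(u), nbh_r(v)). Self pairs (u == v, d = 0) counted once.
//  * hybrid features: for every relation (hyperedge) vertex, its abstract
//    endpoint a and each nucleotide endpoint n give, for every r <= R, a
//    feature keyed by (r, "rel", hybrid, nbh_r(a), nbh_r(n)).
//  * viewpoint restriction: a pair is counted only if u or v (for hybrid: the
//    nucleotide endpoint) carries the viewpoint flag.
//
// nbh_r(u) is a deterministic canonical label of the subgraph induced by the
// vertices reachable from u by <= r traversable directed edges: the sorted
// multiset of per-vertex signatures (distance from root, vertex label, sorted
// multiset of incident in/out edge descriptors within the subgraph).
//
// Relation vertices are never traversable and never roots.

static inline uint64_t fnv1a64(const std::string& s) {
  uint64_t h = 1469598103934665603ULL;
  for (size_t i = 0; i < s.size(); ++i) {
    h ^= (unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  return h;
}


struct AdjGraph {
  int n;
  std::vector<std::string> lab;
  struct Arc { int to; std::string elab; };
  std::vector<std::vector<Arc> > out, in;
};

// BFS from u over traversable edges (directed unless undirected) to depth
// maxd; fills dist (must be -1-initialized) and the list of touched vertices
static void bfs_from(const AdjGraph& G, int u, int maxd, bool undirected,
                     std::vector<int>& dist, std::vector<int>& touched) {
  touched.clear();
  dist[u] = 0; touched.push_back(u);
  std::vector<int> frontier(1, u), nxt;
  for (int dd = 1; dd <= maxd && !frontier.empty(); ++dd) {
    nxt.clear();
    for (size_t q = 0; q < frontier.size(); ++q) {
      int x = frontier[q];
      for (size_t a = 0; a < G.out[x].size(); ++a) {
        int y = G.out[x][a].to;
        if (dist[y] < 0) { dist[y] = dd; touched.push_back(y); nxt.push_back(y); }
      }
      if (undirected) {
        for (size_t a = 0; a < G.in[x].size(); ++a) {
          int y = G.in[x][a].to;
          if (dist[y] < 0) { dist[y] = dd; touched.push_back(y); nxt.push_back(y); }
        }
      }
    }
    frontier = nxt;
  }
}

// canonical label of the radius-r neighborhood subgraph given the current
// BFS distances from the root
static std::string nbh_label_r(const AdjGraph& G, const std::vector<int>& dist,
                               const std::vector<int>& members, int r,
                               bool undirected) {
  std::vector<std::string> sigs;
  for (size_t q = 0; q < members.size(); ++q) {
    int x = members[q];
    if (dist[x] > r) continue;
    std::vector<std::string> desc;
    for (size_t a = 0; a < G.out[x].size(); ++a) {
      int y = G.out[x][a].to;
      if (dist[y] >= 0 && dist[y] <= r) {
        desc.push_back((undirected ? std::string("u,") : std::string("o,")) +
                       G.out[x][a].elab + "," + G.lab[y] + "," +
                       std::to_string(dist[y]));
      }
    }
    for (size_t a = 0; a < G.in[x].size(); ++a) {
      int y = G.in[x][a].to;
      if (dist[y] >= 0 && dist[y] <= r) {
        desc.push_back((undirected ? std::string("u,") : std::string("i,")) +
                       G.in[x][a].elab + "," + G.lab[y] + "," +
                       std::to_string(dist[y]));
      }
    }
    std::sort(desc.begin(), desc.end());
    std::string sg = std::to_string(dist[x]) + "|" + G.lab[x] + "|";
    for (size_t a = 0; a < desc.size(); ++a) { sg += desc[a]; sg += ";"; }
    sigs.push_back(sg);
  }
  std::sort(sigs.begin(), sigs.end());
  std::string full;
  for (size_t q = 0; q < sigs.size(); ++q) { full += sigs[q]; full += "#"; }
  return full;
}

static AdjGraph build_adj(const CharacterVector& labels,
                          const IntegerVector& e_src,
                          const IntegerVector& e_dst,
                          const CharacterVector& e_label,
                          const LogicalVector& e_traversable) {
  AdjGraph G;
  G.n = labels.size();
  G.lab.resize(G.n);
  for (int i = 0; i < G.n; ++i) G.lab[i] = as<std::string>(labels[i]);
  G.out.resize(G.n); G.in.resize(G.n);
  for (int e = 0; e < e_src.size(); ++e) {
    if (!e_traversable[e]) continue;
    int s = e_src[e] - 1, d = e_dst[e] - 1;
    std::string el = as<std::string>(e_label[e]);
    G.out[s].push_back(AdjGraph::Arc{d, el});
    G.in[d].push_back(AdjGraph::Arc{s, el});
  }
  return G;
}

// [[Rcpp::export(name = ".nspdk_neighborhood")]]
std::string nspdk_neighborhood(CharacterVector labels,
                               IntegerVector kind,
                               IntegerVector e_src, IntegerVector e_dst,
                               CharacterVector e_label,
                               LogicalVector e_traversable,
                               int root, int r, bool undirected) {
  if (kind[root - 1] == 2)
    stop("relation vertices are not traversal-eligible roots");
  AdjGraph G = build_adj(labels, e_src, e_dst, e_label, e_traversable);
  std::vector<int> dist(G.n, -1), touched;
  bfs_from(G, root - 1, r, undirected, dist, touched);
  std::vector<int> members(touched);
  std::sort(members.begin(), members.end());
  return nbh_label_r(G, dist, members, r, undirected);
}

// [[Rcpp::export(name = ".nspdk_extract")]]
List nspdk_extract(CharacterVector labels,
                   IntegerVector kind,        // 0 ground, 1 abstract, 2 relation
                   LogicalVector viewpoint,
                   IntegerVector e_src,       // 1-based
                   IntegerVector e_dst,
                   CharacterVector e_label,
                   LogicalVector e_traversable,
                   int R, int D, int bits,
                   bool exact, bool undirected, bool want_occ) {
  const int n = labels.size();
  const int m = e_src.size();
  std::vector<std::string> lab(n);
  for (int i = 0; i < n; ++i) lab[i] = as<std::string>(labels[i]);

  // adjacency over traversable edges
  struct Arc { int to; std::string elab; };
  std::vector<std::vector<Arc> > out(n), in(n);
  // relation links (non-traversable "relation_link" edges), orientation-agnostic
  std::vector<int> rel_abs(n, -1);
  std::vector<std::vector<int> > rel_nuc(n);
  for (int e = 0; e < m; ++e) {
    int s = e_src[e] - 1, d = e_dst[e] - 1;
    std::string el = as<std::string>(e_label[e]);
    if (e_traversable[e]) {
      out[s].push_back(Arc{d, el});
      in[d].push_back(Arc{s, el});
    } else if (el == "relation_link") {
      int rv = -1, other = -1;
      if (kind[s] == 2) { rv = s; other = d; }
      else if (kind[d] == 2) { rv = d; other = s; }
      if (rv >= 0) {
        if (kind[other] == 1) rel_abs[rv] = other;
        else if (kind[other] == 0) rel_nuc[rv].push_back(other);
      }
    }
  }

  const int maxd = std::max(R, D);
  std::vector<int> dist(n, -1);
  std::vector<int> touched;
  std::vector<int> frontier, nxt;

  // neighborhood canonical labels nbh[u][r]
  std::vector<std::vector<std::string> > nbh(n, std::vector<std::string>(R + 1));

  // feature accumulation
  std::unordered_map<std::string, int> key2id;
  std::vector<std::string> keyStr, keyBlock;
  std::vector<double> keyCount;
  std::vector<int> occ_key, occ_u, occ_v;

  // all (root, dist<=D same-kind) pairs are recorded during each BFS, but the
  // nbh label of the partner may not exist yet; store raw pairs first
  struct RawPair { int u, v, d; };
  std::vector<RawPair> rawPairs;

  for (int u = 0; u < n; ++u) {
    if (kind[u] == 2) continue;   // relation vertices are not roots
    // BFS from u over traversable edges (directed unless undirected)
    touched.clear();
    dist[u] = 0; touched.push_back(u);
    frontier.clear(); frontier.push_back(u);
    for (int dd = 1; dd <= maxd && !frontier.empty(); ++dd) {
      nxt.clear();
      for (size_t q = 0; q < frontier.size(); ++q) {
        int x = frontier[q];
        for (size_t a = 0; a < out[x].size(); ++a) {
          int y = out[x][a].to;
          if (dist[y] < 0) { dist[y] = dd; touched.push_back(y); nxt.push_back(y); }
        }
        if (undirected) {
          for (size_t a = 0; a < in[x].size(); ++a) {
            int y = in[x][a].to;
            if (dist[y] < 0) { dist[y] = dd; touched.push_back(y); nxt.push_back(y); }
          }
        }
      }
      frontier = nxt;
    }

    // canonical neighborhood labels for all radii
    // members sorted by id for determinism; signatures sorted at the end
    std::vector<int> members(touched);
    std::sort(members.begin(), members.end());
    for (int r = 0; r <= R; ++r) {
      std::vector<std::string> sigs;
      for (size_t q = 0; q < members.size(); ++q) {
        int x = members[q];
        if (dist[x] > r) continue;
        std::vector<std::string> desc;
        for (size_t a = 0; a < out[x].size(); ++a) {
          int y = out[x][a].to;
          if (dist[y] >= 0 && dist[y] <= r) {
            desc.push_back((undirected ? std::string("u,") : std::string("o,")) +
                           out[x][a].elab + "," + lab[y] + "," +
                           std::to_string(dist[y]));
          }
        }
        for (size_t a = 0; a < in[x].size(); ++a) {
          int y = in[x][a].to;
          if (dist[y] >= 0 && dist[y] <= r) {
            desc.push_back((undirected ? std::string("u,") : std::string("i,")) +
                           in[x][a].elab + "," + lab[y] + "," +
                           std::to_string(dist[y]));
          }
        }
        std::sort(desc.begin(), desc.end());
        std::string sg = std::to_string(dist[x]) + "|" + lab[x] + "|";
        for (size_t a = 0; a < desc.size(); ++a) { sg += desc[a]; sg += ";"; }
        sigs.push_back(sg);
      }
      std::sort(sigs.begin(), sigs.end());
      std::string full;
      for (size_t q = 0; q < sigs.size(); ++q) { full += sigs[q]; full += "#"; }
      if (exact) {
        nbh[u][r] = full;
      } else {
        char buf[17];
        snprintf(buf, sizeof(buf), "%016llx",
                 (unsigned long long)fnv1a64(full));
        nbh[u][r] = buf;
      }
    }

    // record root pairs from this BFS
    for (size_t q = 0; q < touched.size(); ++q) {
      int v = touched[q];
      if (dist[v] > D) continue;
      if (kind[v] != kind[u]) continue;
      if (kind[v] == 2) continue;
      if (!(viewpoint[u] || viewpoint[v])) continue;
      rawPairs.push_back(RawPair{u, v, dist[v]});
    }

    for (size_t q = 0; q < touched.size(); ++q) dist[touched[q]] = -1;
  }

  auto add_feature = [&](const std::string& key, const std::string& block,
                         int u1, int v1) {
    std::unordered_map<std::string, int>::iterator it = key2id.find(key);
    int id;
    if (it == key2id.end()) {
      id = (int)keyStr.size();
      key2id[key] = id;
      keyStr.push_back(key);
      keyBlock.push_back(block);
      keyCount.push_back(0.0);
    } else id = it->second;
    keyCount[id] += 1.0;
    if (want_occ) { occ_key.push_back(id + 1); occ_u.push_back(u1); occ_v.push_back(v1); }
  };

  // pair features
  for (size_t p = 0; p < rawPairs.size(); ++p) {
    int u = rawPairs[p].u, v = rawPairs[p].v, d = rawPairs[p].d;
    std::string set = (kind[u] == 0) ? "g" : "a";
    for (int r = 0; r <= R; ++r) {
      std::string block = "r" + std::to_string(r) + "|d" + std::to_string(d) + "|" + set;
      std::string key = "P\t" + block + "\t" + nbh[u][r] + "\t" + nbh[v][r];
      add_feature(key, block, u + 1, v + 1);
    }
  }

  // hybrid features: relation endpoints
  for (int rv = 0; rv < n; ++rv) {
    if (kind[rv] != 2) continue;
    int a = rel_abs[rv];
    if (a < 0) continue;
    for (size_t q = 0; q < rel_nuc[rv].size(); ++q) {
      int nu = rel_nuc[rv][q];
      if (!viewpoint[nu]) continue;
      for (int r = 0; r <= R; ++r) {
        std::string block = "r" + std::to_string(r) + "|rel|h";
        std::string key = "H\t" + block + "\t" + nbh[a][r] + "\t" + nbh[nu][r];
        add_feature(key, block, a + 1, nu + 1);
      }
    }
  }

  int K = (int)keyStr.size();
  CharacterVector keys(K), blocks(K);
  NumericVector counts(K);
  IntegerVector index(K);
  uint64_t mask = (bits >= 64) ? ~0ULL : ((1ULL << bits) - 1ULL);
  for (int i = 0; i < K; ++i) {
    keys[i] = keyStr[i];
    blocks[i] = keyBlock[i];
    counts[i] = keyCount[i];
    uint64_t h = fnv1a64(keyStr[i]);
    index[i] = (int)(((h ^ (h >> 32)) & mask)) + 1;
  }
  List res = List::create(_["keys"] = keys, _["block"] = blocks,
                          _["count"] = counts, _["index"] = index);
  if (want_occ) {
    res["occ_key"] = IntegerVector(occ_key.begin(), occ_key.end());
    res["occ_u"] = IntegerVector(occ_u.begin(), occ_u.end());
    res["occ_v"] = IntegerVector(occ_v.begin(), occ_v.end());
  }
  return res;
}
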