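// Byte-pair encoding over the DNA alphabet {A,C,G,T}.
//
// Training follows the classic merge loop: repeatedly replace the most
// frequent adjacent token pair with a new composite token.  Ties on
// frequency are broken by the lexicographically smallest merged string so
// training is deterministic for a fixed corpus.  Pair counts are maintained
// incrementally (only positions adjacent to a merge change) with a lazy
// max-heap over (count, merged string), so training is near-linear in the
// corpus instead of rescanning it per merge.  Encoding is greedy
// longest-match over a 4-ary trie; because the four single bases are always
// in the vocabulary, every {A,C,G,T} string segments losslessly.

#include <Rcpp.h>
#include <unordered_map>
#include <queue>
#include <vector>
#include <string>
#include <cstring>

using namespace Rcpp;

static inline int base_id(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

static inline long long pair_key(int a, int b) {
  return (long long)a * 1000000LL + b;
}

struct HeapEntry {
  int count;
  std::string str;  // merged token string, for deterministic tie-breaking
  long long key;
};
struct HeapLess {
  bool operator()(const HeapEntry &x, const HeapEntry &y) const {
    if (x.count != y.count) return x.count < y.count;
    return x.str > y.str;  // smaller string wins ties
  }
};

// [[Rcpp::export]]
CharacterVector bpe_train_cpp(CharacterVector corpus, int n_merges) {
  std::vector<std::string> tokens = {"A", "C", "G", "T"};
  // Token stream with -1 sequence separators; merges never cross them.
  std::vector<int> stream;
  for (R_xlen_t s = 0; s < corpus.size(); ++s) {
    const char *p = CHAR(STRING_ELT(corpus, s));
    for (; *p; ++p) {
      int id = base_id(*p);
      if (id < 0) stop("corpus contains a character outside {A,C,G,T}");
      stream.push_back(id);
    }
    stream.push_back(-1);
  }
  if (stream.empty()) stop("empty corpus");

  // Doubly linked list over the stream so merges are O(1) splices.
  const int n = (int)stream.size();
  std::vector<int> nxt(n), prv(n);
  for (int i = 0; i < n; ++i) { nxt[i] = i + 1 < n ? i + 1 : -1; prv[i] = i - 1; }
  std::vector<bool> dead(n, false);

  std::unordered_map<long long, int> counts;
  std::unordered_map<long long, std::vector<int>> occ;  // left positions
  counts.reserve(1 << 16);
  occ.reserve(1 << 16);
  for (int i = 0; i + 1 < n; ++i)
    if (stream[i] >= 0 && stream[i + 1] >= 0) {
      long long k = pair_key(stream[i], stream[i + 1]);
      ++counts[k];
      occ[k].push_back(i);
    }

  std::priority_queue<HeapEntry, std::vector<HeapEntry>, HeapLess> heap;
  auto push_pair = [&](int a, int b) {
    long long k = pair_key(a, b);
    auto it = counts.find(k);
    if (it != counts.end() && it->second >= 2)
      heap.push({it->second, tokens[a] + tokens[b], k});
  };
  for (const auto &kv : counts) {
    int a = (int)(kv.first / 1000000LL), b = (int)(kv.first % 1000000LL);
    if (kv.second >= 2) heap.push({kv.second, tokens[a] + tokens[b], kv.first});
  }

  auto dec_pair = [&](int a, int b) { --counts[pair_key(a, b)]; };
  auto inc_pair = [&](int a, int b, int pos, std::vector<long long> &touched) {
    long long k = pair_key(a, b);
    ++counts[k];
    occ[k].push_back(pos);
    touched.push_back(k);
  };

  for (int merge = 0; merge < n_merges; ++merge) {
    // Pop until an entry whose count is still current (lazy deletion).
    long long best_key = -1;
    while (!heap.empty()) {
      HeapEntry top = heap.top();
      auto it = counts.find(top.key);
      if (it != counts.end() && it->second == top.count && it->second >= 2) {
        best_key = top.key;
        break;
      }
      heap.pop();
      // count changed since this entry was pushed: re-queue at its current
      // value so pairs whose counts only ever decrease are not lost
      if (it != counts.end() && it->second >= 2 && it->second < top.count)
        heap.push({it->second, top.str, top.key});
    }
    if (best_key < 0) break;  // no pair occurs twice; vocabulary saturated
    heap.pop();
    const int a = (int)(best_key / 1000000LL), b = (int)(best_key % 1000000LL);
    const int z = (int)tokens.size();
    tokens.push_back(tokens[a] + tokens[b]);

    // Merge at every still-valid recorded occurrence (ascending positions,
    // so overlapping runs like AAAA merge left-to-right, non-overlapping);
    // update neighbour pair counts and occurrence lists incrementally.
    std::vector<int> positions;
    positions.swap(occ[best_key]);
    occ.erase(best_key);
    std::sort(positions.begin(), positions.end());
    std::vector<long long> touched;
    for (int i : positions) {
      if (dead[i] || stream[i] != a) continue;
      int j = nxt[i];
      if (j == -1 || dead[j] || stream[j] != b) continue;
      int p = prv[i], q = nxt[j];
      if (p != -1 && !dead[p] && stream[p] >= 0) {
        dec_pair(stream[p], a);
        inc_pair(stream[p], z, p, touched);
      }
      if (q != -1 && !dead[q] && stream[q] >= 0) {
        dec_pair(b, stream[q]);
        inc_pair(z, stream[q], i, touched);
      }
      stream[i] = z;
      dead[j] = true;
      nxt[i] = q;
      if (q != -1) prv[q] = i;
    }
    counts.erase(best_key);
    for (long long k : touched) {
      int x = (int)(k / 1000000LL), y = (int)(k % 1000000LL);
      push_pair(x, y);
    }
  }
  return wrap(tokens);
}

struct TrieNode {
  int child[4];
  int tok;
  TrieNode() : tok(-1) { child[0] = child[1] = child[2] = child[3] = -1; }
};

static std::vector<TrieNode> build_trie(const CharacterVector &tokens,
                                        const IntegerVector &ids) {
  std::vector<TrieNode> trie(1);
  for (R_xlen_t t = 0; t < tokens.size(); ++t) {
    const char *p = CHAR(STRING_ELT(tokens, t));
    int node = 0;
    for (; *p; ++p) {
      int c = base_id(*p);
      if (c < 0) stop("vocabulary token contains a character outside {A,C,G,T}");
      if (trie[node].child[c] < 0) {
        trie[node].child[c] = (int)trie.size();
        trie.push_back(TrieNode());
      }
      node = trie[node].child[c];
    }
    trie[node].tok = ids[t];
  }
  return trie;
}

// Greedy longest-match segmentation. `tokens`/`ids` are parallel vectors
// (ids are the 0-based vocabulary ids used downstream by the encoder).
// [[Rcpp::export]]
List bpe_encode_cpp(CharacterVector seqs, CharacterVector tokens,
                    IntegerVector ids) {
  std::vector<TrieNode> trie = build_trie(tokens, ids);
  List out(seqs.size());
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *str = CHAR(STRING_ELT(seqs, s));
    size_t n = strlen(str);
    std::vector<int> enc;
    enc.reserve(n / 4 + 1);
    size_t i = 0;
    while (i < n) {
      int node = 0, last_tok = -1;
      size_t last_len = 0;
      for (size_t j = i; j < n; ++j) {
        int c = base_id(str[j]);
        if (c < 0) stop("sequence contains a character outside {A,C,G,T}");
        node = trie[node].child[c];
        if (node < 0) break;
        if (trie[node].tok >= 0) {
          last_tok = trie[node].tok;
          last_len = j - i + 1;
        }
      }
      if (last_tok < 0) stop("no vocabulary token matches at position %d", (int)i);
      enc.push_back(last_tok);
      i += last_len;
    }
    out[s] = wrap(enc);
  }
  return out;
}
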