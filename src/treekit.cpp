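// Core hot paths: stack-based Newick parsing/writing and the seeded tree
// simulator.  Everything here is iterative (explicit stacks) so that trees
// with millions of tips, including fully pectinate ones, never touch the
// call stack.

#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <cstdlib>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Newick parsing
// ---------------------------------------------------------------------------

namespace {

struct NodeStore {
  std::vector<int> parent;          // 0-based, -1 for root
  std::vector<std::string> label;
  std::vector<char> has_label;
  std::vector<double> blen;
  std::vector<char> has_len;
  std::vector<std::string> ann;     // raw "[...]" blocks, concatenated
  std::vector<std::string> hybrid;
  std::vector<char> has_hybrid;

  int add(int par) {
    parent.push_back(par);
    label.push_back(std::string());
    has_label.push_back(0);
    blen.push_back(NA_REAL);
    has_len.push_back(0);
    ann.push_back(std::string());
    hybrid.push_back(std::string());
    has_hybrid.push_back(0);
    return static_cast<int>(parent.size()) - 1;
  }
  size_t size() const { return parent.size(); }
};

[[noreturn]] void parse_fail(const std::string& msg, size_t pos) {
  // 1-based character offset, as documented
  stop("Newick parse error at character %d: %s", static_cast<int>(pos) + 1,
       msg.c_str());
}

inline bool is_space(char c) {
  return c == ' ' || c == '\t' || c == '\n' || c == '\r' || c == '\f' ||
         c == '\v';
}

// Characters that terminate an unquoted label.
inline bool is_delim(char c) {
  return c == '(' || c == ')' || c == '[' || c == ']' || c == '{' ||
         c == '}' || c == ':' || c == ';' || c == ',' || c == '=' ||
         is_space(c);
}

// Scan a bracketed comment starting at text[i] == '['.  Returns position one
// past the closing ']'.  BEAST/NHX blocks (leading '&') are appended raw to
// the node's annotation buffer; other comments are discarded.
size_t take_comment(const std::string& text, size_t i, NodeStore& ns,
                    int cur, bool* was_annotation) {
  size_t start = i;
  size_t j = i + 1;
  int depth = 1;
  const size_t n = text.size();
  while (j < n && depth > 0) {
    if (text[j] == '[') ++depth;
    else if (text[j] == ']') --depth;
    ++j;
  }
  if (depth != 0) parse_fail("unterminated '[' comment", start);
  // j is one past ']'
  if (j - start > 2 && text[start + 1] == '&') {
    ns.ann[cur] += text.substr(start, j - start);
    if (was_annotation) *was_annotation = true;
  } else if (was_annotation) {
    *was_annotation = false;
  }
  return j;
}

}  // namespace

// Parse a single Newick statement.  Returns flat pre-order vectors:
// parent (1-based, NA at root), label, length, annotation (raw blocks),
// hybrid id.  Creation order of the stack algorithm is pre-order by
// construction: a node is created when its subtree's text begins.
// [[Rcpp::export]]
List cpp_parse_newick(std::string text) {
  NodeStore ns;
  std::vector<int> stack;
  const size_t n = text.size();

  int cur = ns.add(-1);  // root
  bool just_comma = false;
  bool saw_semi = false;
  bool negative_len = false;
  size_t i = 0;

  while (i < n) {
    char c = text[i];
    if (is_space(c)) { ++i; continue; }

    if (c == '(') {
      if (ns.has_label[cur] || ns.has_len[cur])
        parse_fail("unexpected '(' after label or branch length", i);
      stack.push_back(cur);
      cur = ns.add(cur);
      just_comma = false;
      ++i;
    } else if (c == ',') {
      if (stack.empty()) parse_fail("',' outside parentheses", i);
      if (just_comma) parse_fail("dangling comma", i);
      cur = ns.add(stack.back());
      just_comma = true;
      ++i;
    } else if (c == ')') {
      if (stack.empty()) parse_fail("unbalanced ')'", i);
      if (just_comma) parse_fail("dangling comma before ')'", i);
      cur = stack.back();
      stack.pop_back();
      just_comma = false;
      ++i;
    } else if (c == ';') {
      if (!stack.empty()) parse_fail("unbalanced '(': missing ')'", i);
      if (just_comma) parse_fail("dangling comma before ';'", i);
      saw_semi = true;
      ++i;
      break;
    } else if (c == '[') {
      bool ann = false;
      i = take_comment(text, i, ns, cur, &ann);
      if (ann) just_comma = false;
    } else if (c == ':') {
      if (ns.has_len[cur]) parse_fail("duplicate branch length", i);
      ++i;
      // annotations and whitespace may sit between ':' and the number
      while (i < n && (is_space(text[i]) || text[i] == '[')) {
        if (text[i] == '[') i = take_comment(text, i, ns, cur, nullptr);
        else ++i;
      }
      if (i >= n) parse_fail("expected number after ':'", i - 1);
      const char* p = text.c_str() + i;
      char* endp = nullptr;
      double v = std::strtod(p, &endp);
      if (endp == p) parse_fail("expected number after ':'", i);
      if (v < 0) negative_len = true;
      ns.blen[cur] = v;
      ns.has_len[cur] = 1;
      just_comma = false;
      i += static_cast<size_t>(endp - p);
    } else if (c == '\'') {
      // quoted label; '' escapes a quote
      if (ns.has_label[cur])
        parse_fail("second label for the same node", i);
      size_t start = i;
      std::string lab;
      ++i;
      bool closed = false;
      while (i < n) {
        if (text[i] == '\'') {
          if (i + 1 < n && text[i + 1] == '\'') { lab += '\''; i += 2; }
          else { closed = true; ++i; break; }
        } else {
          lab += text[i];
          ++i;
        }
      }
      if (!closed) parse_fail("unterminated quoted label", start);
      ns.label[cur] = lab;
      ns.has_label[cur] = 1;
      just_comma = false;
    } else {
      // unquoted label, possibly with an extended-Newick #<id> suffix
      if (ns.has_label[cur])
        parse_fail("second label for the same node", i);
      if (ns.has_len[cur])
        parse_fail("label after branch length", i);
      size_t start = i;
      while (i < n && !is_delim(text[i]) && text[i] != '\'') ++i;
      std::string tok = text.substr(start, i - start);
      size_t hash = tok.find('#');
      if (hash != std::string::npos) {
        std::string hid = tok.substr(hash + 1);
        if (hid.empty()) parse_fail("empty hybrid id after '#'", start + hash);
        ns.hybrid[cur] = hid;
        ns.has_hybrid[cur] = 1;
        tok = tok.substr(0, hash);
      }
      if (!tok.empty()) {
        ns.label[cur] = tok;
        ns.has_label[cur] = 1;
      }
      just_comma = false;
    }
  }

  if (!saw_semi) parse_fail("missing ';' terminator", n == 0 ? 0 : n - 1);
  while (i < n) {
    if (!is_space(text[i])) parse_fail("text after ';'", i);
    ++i;
  }
  if (negative_len)
    warning("negative branch length(s) in Newick input; kept as parsed");

  const int N = static_cast<int>(ns.size());
  IntegerVector parent(N);
  CharacterVector label(N), ann(N), hybrid(N);
  NumericVector blen(N);
  for (int k = 0; k < N; ++k) {
    parent[k] = ns.parent[k] < 0 ? NA_INTEGER : ns.parent[k] + 1;
    label[k] = ns.has_label[k] ? String(ns.label[k]) : NA_STRING;
    blen[k] = ns.has_len[k] ? ns.blen[k] : NA_REAL;
    ann[k] = ns.ann[k].empty() ? NA_STRING : String(ns.ann[k]);
    hybrid[k] = ns.has_hybrid[k] ? String(ns.hybrid[k]) : NA_STRING;
  }
  return List::create(_["parent"] = parent, _["label"] = label,
                      _["length"] = blen, _["annotation"] = ann,
                      _["hybrid"] = hybrid);
}

// ---------------------------------------------------------------------------
// Newick writing
// ---------------------------------------------------------------------------

namespace {

// shortest decimal that round-trips; %.15g already trims, so 15..17 covers
// every double
void shortest_g(double v, char* buf, size_t bufsz) {
  for (int prec = 15; prec <= 17; ++prec) {
    std::snprintf(buf, bufsz, "%.*g", prec, v);
    if (std::strtod(buf, nullptr) == v) return;
  }
}

inline void append_elt(std::string& out, const CharacterVector& x, int i) {
  if (x[i] != NA_STRING) out += CHAR(STRING_ELT(x, i));
}

}  // namespace

// Iterative writer, symmetric to the parser.  Per node it emits
// `label_tok  pre_ann  :length  post_ann`; `label_tok` (quoted label plus
// any hybrid tag) comes pre-built from R, lengths are formatted here with
// the shortest round-tripping representation, NA lengths are omitted
// entirely.  Assumes the canonical pre-order layout (root first, siblings
// in index order).
// [[Rcpp::export]]
std::string cpp_write_newick(IntegerVector parent, CharacterVector label_tok,
                             NumericVector len,
                             Nullable<CharacterVector> pre_ann,
                             Nullable<CharacterVector> post_ann) {
  const int N = parent.size();
  if (N == 0) return ";";
  CharacterVector pre = pre_ann.isNotNull() ? CharacterVector(pre_ann)
                                            : CharacterVector(0);
  CharacterVector post = post_ann.isNotNull() ? CharacterVector(post_ann)
                                              : CharacterVector(0);
  char numbuf[40];
  // per-node suffix emitter
  auto emit_suffix = [&](std::string& out, int node) {
    append_elt(out, label_tok, node);
    if (pre.size()) append_elt(out, pre, node);
    if (!NumericVector::is_na(len[node])) {
      out += ':';
      shortest_g(len[node], numbuf, sizeof(numbuf));
      out += numbuf;
    }
    if (post.size()) append_elt(out, post, node);
  };

  // children via counting sort: pre-order index order == sibling order
  std::vector<int> cnt(N, 0);
  for (int k = 1; k < N; ++k) cnt[parent[k] - 1]++;
  std::vector<int> start(N + 1, 0);
  for (int k = 0; k < N; ++k) start[k + 1] = start[k] + cnt[k];
  std::vector<int> child(N - 1 > 0 ? N - 1 : 0);
  std::vector<int> fill(start.begin(), start.end() - 1);
  for (int k = 1; k < N; ++k) child[fill[parent[k] - 1]++] = k;

  std::string out;
  out.reserve(static_cast<size_t>(N) * 8 + 16);

  std::vector<std::pair<int, int> > st;  // (node, next child slot)
  st.push_back(std::make_pair(0, 0));
  while (!st.empty()) {
    int node = st.back().first;
    int nx = st.back().second;
    int nc = cnt[node];
    if (nc == 0) {
      emit_suffix(out, node);
      st.pop_back();
      continue;
    }
    if (nx == 0) out += '(';
    if (nx < nc) {
      if (nx > 0) out += ',';
      st.back().second = nx + 1;
      st.push_back(std::make_pair(child[start[node] + nx], 0));
    } else {
      out += ')';
      emit_suffix(out, node);
      st.pop_back();
    }
  }
  out += ';';
  return out;
}

// Shortest decimal representation that round-trips to the same double.
// [[Rcpp::export]]
CharacterVector cpp_format_shortest(NumericVector x) {
  const int n = x.size();
  CharacterVector out(n);
  char buf[40];
  for (int i = 0; i < n; ++i) {
    double v = x[i];
    if (NumericVector::is_na(v)) { out[i] = NA_STRING; continue; }
    shortest_g(v, buf, sizeof(buf));
    out[i] = buf;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Seeded simulator (splitmix64 — deterministic across platforms, independent
// of R's global RNG state)
// ---------------------------------------------------------------------------

namespace {

struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    s += 0x9E3779B97f4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform on (0,1): 53-bit mantissa, never exactly 0
  double u01() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // uniform integer in [0, m)
  int below(int m) {
    return static_cast<int>(u01() * m) % m;
  }
};

}  // namespace

// Deterministic uniform(0,1) stream for R-side generation code.
// [[Rcpp::export]]
NumericVector cpp_runif(int n, double seed) {
  SplitMix64 rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.u01();
  return out;
}

// Random-join binary tree with n_tips leaves.
//  ultrametric = false: every non-root branch length iid Exponential(mean).
//  ultrametric = true : coalescent-style pure-birth construction — with k
//    lineages extant the next join is Exp(rate = k) deeper; node heights are
//    measured from the tips so all leaves sit at height 0 (ultrametric).
// Returns pre-order parent (1-based, NA at root) and branch lengths (NA at
// root); leaves are identifiable as nodes with no children.
// [[Rcpp::export]]
List cpp_sim_tree(int n_tips, double seed, double mean, bool ultrametric) {
  if (n_tips < 1) stop("n_tips must be >= 1");
  SplitMix64 rng(static_cast<uint64_t>(seed));

  const int N = 2 * n_tips - 1;
  std::vector<int> child1(N, -1), child2(N, -1);
  std::vector<double> len(N, NA_REAL), height(N, 0.0);

  std::vector<int> active(n_tips);
  for (int i = 0; i < n_tips; ++i) active[i] = i;
  int next_id = n_tips;
  int k = n_tips;
  double t = 0.0;

  while (k > 1) {
    int i = rng.below(k);
    int j = rng.below(k - 1);
    if (j >= i) ++j;
    int a = active[i], b = active[j];
    int m = next_id++;
    child1[m] = a;
    child2[m] = b;
    if (ultrametric) {
      t += -std::log(rng.u01()) / k;
      height[m] = t;
      len[a] = t - height[a];
      len[b] = t - height[b];
    } else {
      len[a] = -mean * std::log(rng.u01());
      len[b] = -mean * std::log(rng.u01());
    }
    active[i] = m;
    active[j] = active[k - 1];
    --k;
  }
  int root = active[0];

  // pre-order renumber with an explicit stack
  IntegerVector parent(N);
  NumericVector blen(N);
  std::vector<int> newid(N, -1);
  std::vector<int> st;
  st.reserve(64);
  st.push_back(root);
  int nxt = 0;
  while (!st.empty()) {
    int v = st.back();
    st.pop_back();
    newid[v] = nxt++;
    if (child1[v] >= 0) {
      // push right child first so the left is visited first
      st.push_back(child2[v]);
      st.push_back(child1[v]);
    }
  }
  for (int v = 0; v < N; ++v) {
    int id = newid[v];
    parent[id] = NA_INTEGER;  // fixed below for non-roots
    blen[id] = len[v];
  }
  for (int v = 0; v < N; ++v) {
    if (child1[v] >= 0) {
      parent[newid[child1[v]]] = newid[v] + 1;
      parent[newid[child2[v]]] = newid[v] + 1;
    }
  }
  parent[newid[root]] = NA_INTEGER;
  return List::create(_["parent"] = parent, _["length"] = blen);
}
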