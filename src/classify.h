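#ifndef PLUMOTIF_CLASSIFY_H
#define PLUMOTIF_CLASSIFY_H

#include <vector>

// Allocation-free loop-context classification of a partner vector.
// Category codes: 0 paired, 1 hairpin loop, 2 external, 3 bulge,
// 4 internal loop, 5 multiloop. Buffers are reused across calls.
struct ContextClassifier {
  std::vector<int> owner;        // innermost enclosing open index, -1 = root
  std::vector<int> n_children;   // helices directly inside loop keyed by open
  std::vector<int> first_a, first_b;  // first (only) child pair of a loop
  std::vector<int> close_of;     // closing index of the loop keyed by open
  std::vector<int> loop_cat;     // category of unpaired bases in the loop
  std::vector<int> stack;

  void classify(const std::vector<int>& partner, std::vector<int>& cat) {
    int n = (int)partner.size();
    owner.assign(n, -1);
    n_children.assign(n + 1, 0);
    first_a.assign(n + 1, -1);
    first_b.assign(n + 1, -1);
    close_of.assign(n + 1, n);
    loop_cat.assign(n + 1, 2);
    cat.assign(n, 2);
    stack.clear();
    // root loop keyed by index n
    for (int i = 0; i < n; ++i) {
      int cur = stack.empty() ? n : stack.back();
      if (partner[i] > i) {           // helix opens: child of current loop
        if (n_children[cur] == 0) { first_a[cur] = i; first_b[cur] = partner[i]; }
        ++n_children[cur];
        close_of[i] = partner[i];
        stack.push_back(i);
        cat[i] = 0;
      } else if (partner[i] >= 0) {   // helix closes
        cat[i] = 0;
        stack.pop_back();
      } else {
        owner[i] = cur;
      }
    }
    for (int p = 0; p <= n; ++p) {
      if (p < n && partner[p] <= p && p != n) continue;  // not a loop key
      int code;
      if (p == n) {
        code = 2;  // external
      } else if (n_children[p] == 0) {
        code = 1;  // hairpin
      } else if (n_children[p] >= 2) {
        code = 5;  // multiloop
      } else {
        int a = first_a[p], b = first_b[p], q = close_of[p];
        bool left = (a > p + 1), right = (q > b + 1);
        code = (left && right) ? 4 : 3;
      }
      loop_cat[p] = code;
    }
    for (int i = 0; i < n; ++i) {
      if (partner[i] < 0) cat[i] = loop_cat[owner[i]];
    }
  }
};

#endif
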