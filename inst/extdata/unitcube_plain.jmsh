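{"MeshVertex3":[[0,0,0],[1,0,0],[1,1,0],[0,1,0],[0,0,1],[1,0,1],[1,1,1],[0,1,1]],"MeshTri3":[[2,3,7],[2,7,6],[4,7,3],[4,8,7],[5,6,7],[5,7,8],[1,2,6],[1,4,3],[1,5,8],[1,3,2],[1,8,4],[1,6,5]],"MeshTet4":[[1,2,3,7,1],[1,2,7,6,1],[1,4,7,3,1],[1,4,8,7,1],[1,5,6,7,1],[1,5,7,8,1]],"LengthUnit":"mm","Comment":"unit cube: 8 nodes, 12 surface triangles, 6 tetrahedra"}
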